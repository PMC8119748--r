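#' Parse a bin label into its condition factors
#'
#' @param bin Character vector of bin labels (`target_simple_single`, ...).
#' @return Data.frame with `is_target`, `scene`, `task`.
#' @export
parse_bin <- function(bin) {
  parts <- strsplit(bin, "_", fixed = TRUE)
  data.frame(is_target = vapply(parts, `[`, "", 1) == "target",
             scene = vapply(parts, `[`, "", 2),
             task = vapply(parts, `[`, "", 3),
             stringsAsFactors = FALSE)
}

# 31-bit polynomial rolling hash of a string (manifest fingerprinting).
.str_hash <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

.gcd <- function(a, b) if (b == 0) a else .gcd(b, a %% b)

config_hash <- function(config) {
  .str_hash(as.character(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                                          digits = NA)))
}

#' Run the full synthetic experiment end to end
#'
#' Orchestrates all stages: stimulus generation + scoring + iterative IQR
#' screening + design assembly; per-participant session synthesis and
#' preprocessing; cluster bin averages and grand averages; the
#' scene-contrast pointwise t-test trace and jackknife latency test on the
#' centro-parietal CPP; behavioral summary and condition comparisons. A run
#' manifest records the configuration hash, master seed, per-stage counts
#' and package version; deterministic stages reproduce byte-identically
#' under the same manifest inputs.
#'
#' @param config A [synth_config()].
#' @param out_dir Output directory (created); `NULL` to skip writing files.
#' @param design_params List controlling the stimulus-design stage:
#'   `n_patches_per_type` (generated pool per type), `practicing_per_type`,
#'   `n_single_blocks`, `n_dual_blocks`. The full-size paradigm corresponds
#'   to `list(n_patches_per_type = 340, practicing_per_type = 20,
#'   n_single_blocks = 3, n_dual_blocks = 5)` balanced to 320 per type;
#'   the default is a desk-scale profile.
#' @param verbose Log per-stage counts to stderr.
#' @return List with `manifest`, `behavior` (`behavior_summary`),
#'   `behavior_tests`, `grand_averages` (bin x cluster), `scene_ttest`,
#'   `scene_jackknife`, `peaks` (per-participant CPP peak table), `design`,
#'   `qc` (per-participant rejection fractions).
#' @export
run_end_to_end <- function(config, out_dir = NULL,
                           design_params = list(n_patches_per_type = 44,
                                                practicing_per_type = 20,
                                                n_single_blocks = 1,
                                                n_dual_blocks = 1),
                           verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- Sys.time()

  ## stage 1: stimuli -> scores -> screen -> design
  say("[stimuli] generating %d patches/type", design_params$n_patches_per_type)
  patches <- generate_stimulus_set(design_params$n_patches_per_type,
                                   seed = sub_seed(config$seed, "stimuli"))
  scores <- score_patches(patches)
  screened <- iterative_iqr_screen(scores)
  # trim to the largest per-type count whose testing trials split evenly
  # over tasks, sessions, blocks and the question scheduler
  min_count <- min(table(screened$kept$type_label))
  pr <- design_params$practicing_per_type
  lcm2 <- function(a, b) a * b / .gcd(a, b)
  need <- Reduce(lcm2, c(12,
                         design_params$n_single_blocks %/% .gcd(2, design_params$n_single_blocks),
                         design_params$n_dual_blocks %/% .gcd(2, design_params$n_dual_blocks)))
  t_use <- need * ((min_count - pr) %/% need)
  if (t_use < need) stop("too few patches survive screening for the design")
  balanced <- balance_types(screened$kept,
                            seed = sub_seed(config$seed, "screen"),
                            n = pr + t_use)
  design <- assemble_design(balanced,
                            practicing_per_type = design_params$practicing_per_type,
                            n_single_blocks = design_params$n_single_blocks,
                            n_dual_blocks = design_params$n_dual_blocks,
                            seed = sub_seed(config$seed, "design"))
  say("[screen] kept %d / %d patches in %d passes; testing trials %d (%d target)",
      nrow(screened$kept), nrow(scores), screened$n_passes,
      nrow(design$testing), design$counts$n_target)

  ## stage 2: sessions -> preprocessing -> bin averages
  clusters <- list(occipital = cluster_spec("occipital"),
                   `centro-parietal` = cluster_spec("centro-parietal"))
  erps <- list(occipital = list(), `centro-parietal` = list())
  behavior <- list(); qc <- numeric(config$n_participants)
  for (i in seq_len(config$n_participants)) {
    ses <- generate_session(config, i)
    ep <- preprocess_session(ses, band = config$band_hz)
    qc[i] <- mean(ep$rejected)
    pid <- sprintf("P%02d", i)
    for (cl in names(clusters))
      erps[[cl]][[pid]] <- bin_average(ep, clusters[[cl]], pid)
    ev <- ses$events
    fac <- parse_bin(ev$bin)
    behavior[[pid]] <- data.frame(participant = pid, bin = ev$bin, fac,
                                  rt_s = ev$rt_s, correct = ev$correct,
                                  question = ev$question,
                                  question_correct = ev$question_correct,
                                  stringsAsFactors = FALSE)
    say("[session %s] %d events, %.1f%% epochs flagged", pid, nrow(ev),
        100 * qc[i])
  }
  records <- do.call(rbind, behavior)
  rownames(records) <- NULL

  ## stage 3: statistics
  bins <- condition_bins()
  time_ms <- erps[[1]][[1]]$time_ms
  grand <- list()
  for (cl in names(clusters))
    for (b in bins$bin) {
      m <- erp_stack(erps[[cl]], b)
      grand[[paste(cl, b, sep = "|")]] <- colMeans(m)
    }
  simple_bins <- bins$bin[bins$scene == "simple"]
  complex_bins <- bins$bin[bins$scene == "complex"]
  cp <- erps[["centro-parietal"]]
  A <- erp_stack(cp, simple_bins); B <- erp_stack(cp, complex_bins)
  scene_ttest <- pointwise_fdr_ttest(A, B, time_ms)
  scene_jack <- if (nrow(A) >= 3 && nrow(B) >= 3)
    jackknife_latency_test(A, B, time_ms, component = "CPP") else NULL

  peaks <- do.call(rbind, lapply(names(cp), function(pid) {
    do.call(rbind, lapply(names(cp[[pid]]$waveforms), function(b) {
      pm <- peak_measure(cp[[pid]]$waveforms[[b]], time_ms, "CPP")
      data.frame(participant = pid, bin = b, cluster = "centro-parietal",
                 latency_ms = pm$latency_ms, amplitude_uv = pm$amplitude,
                 stringsAsFactors = FALSE)
    }))
  }))

  bsum <- summarize_behavior(records)
  # degenerate contrasts (e.g. ceiling accuracy in tiny runs) are reported
  # as NULL rather than aborting the bundle
  safe_cmp <- function(...) tryCatch(compare_behavior(...),
                                     error = function(e) NULL)
  btests <- list(rt_scene = safe_cmp(records, "scene", "rt"),
                 rt_task = safe_cmp(records, "task", "rt"),
                 acc_scene = safe_cmp(records, "scene", "detection_acc"))

  manifest <- list(
    package_version = as.character(utils::packageVersion("erpscene")),
    config_hash = config_hash(config),
    master_seed = config$seed,
    stages = list(
      stimuli = list(n_generated = nrow(scores), n_kept = nrow(screened$kept),
                     n_passes = screened$n_passes),
      design = list(n_testing = nrow(design$testing),
                    n_target = design$counts$n_target,
                    n_nontarget = design$counts$n_nontarget),
      sessions = list(n_participants = config$n_participants,
                      n_events = nrow(records),
                      mean_reject_fraction = mean(qc)),
      stats = list(n_bins = length(bins$bin), n_clusters = length(clusters))))

  result <- list(manifest = manifest, behavior = bsum, behavior_tests = btests,
                 grand_averages = grand, time_ms = time_ms,
                 scene_ttest = scene_ttest, scene_jackknife = scene_jack,
                 peaks = peaks, design = design, qc = qc)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(records, file.path(out_dir, "behavior_records.csv"),
                     row.names = FALSE)
    utils::write.csv(bsum$group, file.path(out_dir, "behavior_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(peaks, file.path(out_dir, "cpp_peaks.csv"),
                     row.names = FALSE)
    ga <- do.call(rbind, lapply(names(grand), function(k) {
      parts <- strsplit(k, "|", fixed = TRUE)[[1]]
      data.frame(cluster = parts[1], bin = parts[2], time_ms = time_ms,
                 amplitude_uv = grand[[k]], stringsAsFactors = FALSE)
    }))
    utils::write.csv(ga, file.path(out_dir, "grand_averages.csv"),
                     row.names = FALSE)
    stats_json <- list(
      scene_ttest = list(q = scene_ttest$q, intervals = scene_ttest$intervals),
      scene_jackknife = if (is.null(scene_jack)) NULL else
        scene_jack[c("difference", "se", "t", "df", "p")],
      qc = list(mean_reject_fraction = mean(qc)))
    jsonlite::write_json(stats_json, file.path(out_dir, "stats.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  say("[done] %.1f s", as.numeric(difftime(Sys.time(), t0, units = "secs")))
  result
}
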