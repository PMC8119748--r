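#' Configuration for the synthetic experiment generator
#'
#' Builds the parameter set from which stimulus patches, continuous EEG with
#' events, and behavioral records are simulated. Defaults encode the study
#' conditions the analysis targets: 48 participants, a 63-channel 10-10
#' montage referenced to Iz at 1000 Hz, a late occipital positivity (LOP)
#' peaking near 350 ms, a centro-parietal positivity (CPP) peaking at 520 ms
#' (simple scenes) vs 608 ms (complex scenes) pooled over tasks (single task
#' 20 ms earlier, dual task 20 ms later than the scene mean), reaction times
#' and accuracies per condition matching the behavioral summary table of the
#' paradigm (simple/single 0.599 s ... complex/dual 1.267 s; detection
#' accuracy 0.970-0.992; scene-similarity accuracy 0.857/0.853), and an
#' inter-stimulus interval uniform on 1.25-1.5 s.
#'
#' Per-bin component parameters are named numeric vectors over the 8 bins of
#' [condition_bins()]. Per-participant random effects (normal latency and
#' amplitude offsets, drawn once per participant) create realistic group
#' dispersion.
#'
#' @param n_participants Number of simulated participants.
#' @param n_trials_per_bin Trials per experimental bin per participant.
#' @param sampling_rate Recording rate in Hz.
#' @param montage Character vector of scalp channel labels.
#' @param reference Label of the recording reference electrode.
#' @param lop_params,cpp_params Lists with per-bin `latency_ms` and
#'   `amplitude_uv` (named numeric over bins), scalar `width_ms` (Gaussian
#'   SD), and per-participant random-effect SDs `participant_latency_sd_ms`,
#'   `participant_amplitude_sd_uv`.
#' @param noise List: `pink_sd` and `white_sd` in microvolts (per channel,
#'   single trial), `pink_exponent` (power-spectral slope, power ~ 1/f^e).
#' @param artifact_rate Probability that an epoch receives a blink artifact.
#' @param blink_amplitude_uv Peak amplitude of the frontal blink template.
#' @param behavior_params List of per-condition reaction-time and accuracy
#'   parameters; see Details in the package vignette.
#' @param isi_range Inter-stimulus interval range in seconds.
#' @param band_hz Analysis band-pass in Hz (validated against Nyquist).
#' @param couple_rt_to_cpp If `TRUE`, trial RT is the trial's CPP latency
#'   plus lognormal noise instead of an independent draw.
#' @param seed Master integer seed; all randomness derives from it.
#' @return An object of class `synth_config`.
#' @examples
#' cfg <- synth_config(n_participants = 2, n_trials_per_bin = 4)
#' cfg$cpp_params$latency_ms
#' @export
synth_config <- function(n_participants = 48,
                         n_trials_per_bin = 16,
                         sampling_rate = 1000,
                         montage = montage_1010(),
                         reference = "Iz",
                         lop_params = NULL,
                         cpp_params = NULL,
                         noise = list(pink_sd = 8, white_sd = 4, pink_exponent = 1),
                         artifact_rate = 0.05,
                         blink_amplitude_uv = 100,
                         behavior_params = NULL,
                         isi_range = c(1.25, 1.5),
                         band_hz = c(0.5, 100),
                         couple_rt_to_cpp = FALSE,
                         seed = 1L) {
  bins <- condition_bins()
  bn <- bins$bin

  if (is.null(lop_params)) {
    amp <- ifelse(bins$is_target, 6.5, 4.0) +
      ifelse(!bins$is_target & bins$scene == "complex", 1.2, 0) -
      ifelse(bins$task == "dual", 0.8, 0)
    lop_params <- list(
      latency_ms = stats::setNames(rep(350, 8), bn),
      amplitude_uv = stats::setNames(amp, bn),
      width_ms = 50,
      participant_latency_sd_ms = 15,
      participant_amplitude_sd_uv = 0.8)
  }
  if (is.null(cpp_params)) {
    lat <- ifelse(bins$scene == "simple", 520, 608) +
      ifelse(bins$task == "dual", 20, -20)
    amp <- ifelse(bins$is_target, 8,
                  ifelse(bins$task == "dual", 6.5, 5))
    cpp_params <- list(
      latency_ms = stats::setNames(lat, bn),
      amplitude_uv = stats::setNames(amp, bn),
      width_ms = 60,
      participant_latency_sd_ms = 25,
      participant_amplitude_sd_uv = 1.0)
  }
  if (is.null(behavior_params)) {
    cond <- c("single_simple", "single_complex", "dual_simple", "dual_complex")
    behavior_params <- list(
      rt_mean_s = stats::setNames(c(0.599, 0.811, 0.998, 1.267), cond),
      rt_between_cv = stats::setNames(c(0.092, 0.190, 0.344, 0.446) /
                                        c(0.599, 0.811, 0.998, 1.267), cond),
      rt_trial_sigma = 0.25,
      detection_acc = stats::setNames(c(0.992, 0.970, 0.990, 0.978), cond),
      similarity_acc = c(simple = 0.857, complex = 0.853),
      similarity_between_sd = 0.067)
  }

  cfg <- structure(list(
    n_participants = as.integer(n_participants),
    n_trials_per_bin = as.integer(n_trials_per_bin),
    sampling_rate = sampling_rate,
    montage = montage,
    reference = reference,
    lop_params = lop_params,
    cpp_params = cpp_params,
    noise = noise,
    artifact_rate = artifact_rate,
    blink_amplitude_uv = blink_amplitude_uv,
    behavior_params = behavior_params,
    isi_range = isi_range,
    band_hz = band_hz,
    couple_rt_to_cpp = isTRUE(couple_rt_to_cpp),
    seed = as.integer(seed)),
    class = "synth_config")
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  stopifnot(
    cfg$n_participants >= 1,
    cfg$n_trials_per_bin >= 1,
    cfg$sampling_rate > 0,
    !anyDuplicated(cfg$montage),
    length(cfg$isi_range) == 2, diff(cfg$isi_range) >= 0, cfg$isi_range[1] > 0)
  rates <- c(cfg$artifact_rate,
             cfg$behavior_params$detection_acc,
             cfg$behavior_params$similarity_acc)
  if (any(rates < 0 | rates > 1))
    stop("all probabilities/rates must lie in [0, 1]")
  lats <- c(cfg$lop_params$latency_ms, cfg$cpp_params$latency_ms)
  if (any(lats <= 0 | lats >= 1000))
    stop("component latencies must lie inside the (0, 1000) ms epoch window")
  if (cfg$lop_params$width_ms <= 0 || cfg$cpp_params$width_ms <= 0)
    stop("component widths must be positive")
  if (cfg$sampling_rate <= 2 * cfg$band_hz[2])
    stop("sampling_rate must exceed twice the band-pass upper edge")
  invisible(cfg)
}

#' @export
print.synth_config <- function(x, ...) {
  cat("<synth_config>\n")
  cat(sprintf("  participants: %d, trials/bin: %d, rate: %g Hz, channels: %d (+%s ref)\n",
              x$n_participants, x$n_trials_per_bin, x$sampling_rate,
              length(x$montage), x$reference))
  cat(sprintf("  CPP latency (ms): simple %s / complex %s (pooled over tasks: %g / %g)\n",
              paste(unique(x$cpp_params$latency_ms[grep("_simple_", names(x$cpp_params$latency_ms))]), collapse = "|"),
              paste(unique(x$cpp_params$latency_ms[grep("_complex_", names(x$cpp_params$latency_ms))]), collapse = "|"),
              mean(x$cpp_params$latency_ms[grep("_simple_", names(x$cpp_params$latency_ms))]),
              mean(x$cpp_params$latency_ms[grep("_complex_", names(x$cpp_params$latency_ms))])))
  cat(sprintf("  noise: pink %g uV, white %g uV; artifact rate %g; ISI %g-%g s; seed %d\n",
              x$noise$pink_sd, x$noise$white_sd, x$artifact_rate,
              x$isi_range[1], x$isi_range[2], x$seed))
  invisible(x)
}

# Deterministic fan-out of the master seed to stages/participants.
# Documented scheme: seed(stage, i) = (master*1103 + id(stage)*10007 + i*101)
# mod 2147483629 (a prime below 2^31), so every consumer gets an independent,
# reproducible stream.
.stage_ids <- c(stimuli = 1, session = 2, behavior = 3, screen = 4,
                design = 5, erp = 6, mc = 7)

sub_seed <- function(master, stage, index = 0L) {
  id <- .stage_ids[[stage]]
  as.integer((as.numeric(master) * 1103 + id * 10007 + as.numeric(index) * 101) %%
               2147483629)
}
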