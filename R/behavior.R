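#' Summarize behavioral records per condition
#'
#' For each participant x task x scene cell: mean detection reaction time
#' over correct detection trials, detection accuracy over all trials, and
#' (dual task) scene-similarity correction rate over question trials. Group
#' rows then give the across-participant mean and SD of the
#' per-participant values.
#'
#' @param records Behavioral records: data.frame with `participant`, `task`,
#'   `scene`, `is_target`, `rt_s`, `correct`, `question`,
#'   `question_correct` (as produced by [generate_behavior_records()] or
#'   read from CSV).
#' @return A `behavior_summary`: list with `per_participant` and `group`
#'   data.frames. RT means are computed over correct trials only (flagged in
#'   the `rt_basis` attribute).
#' @export
summarize_behavior <- function(records) {
  stopifnot(nrow(records) > 0)
  key <- interaction(records$participant, records$task, records$scene,
                     drop = TRUE)
  per <- do.call(rbind, lapply(split(records, key), function(d) {
    qd <- d[d$question %in% TRUE, ]
    data.frame(
      participant = d$participant[1], task = d$task[1], scene = d$scene[1],
      n_trials = nrow(d),
      rt_mean_s = mean(d$rt_s[d$correct]),
      detection_acc = mean(d$correct),
      similarity_rate = if (nrow(qd)) mean(qd$question_correct) else NA_real_,
      stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL
  gkey <- interaction(per$task, per$scene, drop = TRUE)
  group <- do.call(rbind, lapply(split(per, gkey), function(d) {
    data.frame(
      task = d$task[1], scene = d$scene[1], n_participants = nrow(d),
      rt_mean_s = mean(d$rt_mean_s), rt_sd_s = stats::sd(d$rt_mean_s),
      detection_acc = mean(d$detection_acc),
      detection_acc_sd = stats::sd(d$detection_acc),
      similarity_rate = mean(d$similarity_rate),
      similarity_rate_sd = stats::sd(d$similarity_rate),
      stringsAsFactors = FALSE)
  }))
  rownames(group) <- NULL
  out <- structure(list(per_participant = per, group = group),
                   class = "behavior_summary")
  attr(out, "rt_basis") <- "correct detection trials only"
  out
}

#' @export
print.behavior_summary <- function(x, ...) {
  cat("<behavior_summary> group means +/- SD across participants\n")
  g <- x$group
  for (i in seq_len(nrow(g))) {
    cat(sprintf("  %s / %s: RT %.3f +/- %.3f s, Acc-VD %.3f +/- %.3f",
                g$task[i], g$scene[i], g$rt_mean_s[i], g$rt_sd_s[i],
                g$detection_acc[i], g$detection_acc_sd[i]))
    if (is.finite(g$similarity_rate[i]))
      cat(sprintf(", Acc-SJ %.3f +/- %.3f", g$similarity_rate[i],
                  g$similarity_rate_sd[i]))
    cat("\n")
  }
  invisible(x)
}

#' Compare behavioral measures between conditions or groups
#'
#' Two-tailed two-sample t-test (equal variances) on per-participant summary
#' values between the two levels of a contrast. Condition contrasts
#' (`scene`, `task`) compare each participant's per-level summaries as two
#' samples, mirroring the two-sample treatment of within-participant
#' contrasts used in this paradigm; `target` contrasts detection accuracy
#' between target and non-target trials; any other column of `records` with
#' exactly two levels (e.g. a gender or keystroke-hand grouping) is treated
#' as a between-participant grouping.
#'
#' @param records Behavioral records (see [summarize_behavior()]).
#' @param contrast Column name: `"scene"`, `"task"`, `"target"`, or a
#'   two-level grouping column.
#' @param measure `"rt"`, `"detection_acc"` or `"similarity_rate"`.
#' @return List of class `behavior_test`: `t`, `df`, `p`, `levels`,
#'   per-level `means` and `sds`.
#' @export
compare_behavior <- function(records,
                             contrast = c("scene", "task", "target"),
                             measure = c("rt", "detection_acc",
                                         "similarity_rate")) {
  measure <- match.arg(measure)
  if (length(contrast) > 1) contrast <- contrast[1]
  col <- if (contrast == "target") {
    factor(ifelse(records$is_target, "target", "nontarget"),
           c("target", "nontarget"))
  } else factor(records[[contrast]])
  lev <- levels(col)
  if (length(lev) != 2) stop("contrast must have exactly two levels")

  value_of <- function(d) {
    switch(measure,
           rt = mean(d$rt_s[d$correct]),
           detection_acc = mean(d$correct),
           similarity_rate = {
             qd <- d[d$question %in% TRUE, ]
             if (nrow(qd)) mean(qd$question_correct) else NA_real_
           })
  }
  vals <- lapply(lev, function(l) {
    d <- records[col == l, ]
    v <- vapply(split(d, d$participant), value_of, numeric(1))
    v[is.finite(v)]
  })
  if (any(vapply(vals, length, 1L) < 2))
    stop("need at least 2 participants per side")
  tt <- stats::t.test(vals[[1]], vals[[2]], var.equal = TRUE)
  structure(list(contrast = contrast, measure = measure, levels = lev,
                 means = vapply(vals, mean, 1), sds = vapply(vals, stats::sd, 1),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value),
            class = "behavior_test")
}

#' @export
print.behavior_test <- function(x, ...) {
  cat(sprintf("<behavior_test> %s by %s: %s %.3f +/- %.3f vs %s %.3f +/- %.3f\n",
              x$measure, x$contrast, x$levels[1], x$means[1], x$sds[1],
              x$levels[2], x$means[2], x$sds[2]))
  cat(sprintf("  t(%g) = %.3f, two-tailed p = %.4g\n", x$df, x$t, x$p))
  invisible(x)
}
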