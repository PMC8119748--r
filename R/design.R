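#' Assemble the oddball stimulus design
#'
#' Builds practicing and testing trial tables from a balanced patch pool.
#' With the default counts (320 patches per type, 20 per type for
#' practicing) this reproduces the canonical arithmetic of the paradigm:
#' the 300 remaining target patches per complexity level each appear once
#' and the 300 non-target patches per complexity three times (distinct
#' random rotations), giving 600 target and 1,800 non-target testing trials
#' (a 1:3 oddball ratio). Trials are split equally by type between the two
#' tasks, then between the two sessions, then randomized into three
#' 200-trial single-task blocks or five 120-trial dual-task blocks per
#' session. One third of each dual-task session's trials (50 per type by
#' default) are flagged for a scene-similarity question, assigned randomly
#' within type.
#'
#' @param balanced Balanced score table ([balance_types()]); equal per-type
#'   counts required.
#' @param practicing_per_type Patches per type reserved for practicing.
#' @param n_single_blocks,n_dual_blocks Testing blocks per session and task.
#' @param n_sessions Number of sessions.
#' @param seed Integer seed for all selections, rotations and orderings.
#' @return A `stimulus_set`: list with `practicing` and `testing`
#'   data.frames and a `counts` summary.
#' @export
assemble_design <- function(balanced, practicing_per_type = 20L,
                            n_single_blocks = 3L, n_dual_blocks = 5L,
                            n_sessions = 2L, seed = 1L) {
  types <- sort(unique(balanced$type_label))
  counts <- table(balanced$type_label)
  if (length(unique(counts)) != 1)
    stop("per-type counts are unequal; run balance_types() first")
  per_type <- unname(counts[1])
  if (per_type <= practicing_per_type)
    stop("not enough patches per type after reserving the practicing set")
  set.seed(as.integer(seed))
  rotations <- c(0, 90, 180, 270)

  practicing <- list(); testing <- list()
  for (ty in types) {
    rows <- balanced[balanced$type_label == ty, ]
    pr_idx <- sample(nrow(rows), practicing_per_type)
    pr <- rows[pr_idx, ]
    te <- rows[-pr_idx, ]
    if (practicing_per_type %% 2 != 0)
      stop("practicing_per_type must split evenly between the two tasks")
    task_pr <- sample(rep(c("single", "dual"), practicing_per_type / 2))
    practicing[[ty]] <- data.frame(
      patch_id = pr$patch_id, type_label = ty,
      is_target = grepl("-target$", ty), complexity = sub("-.*", "", ty),
      rotation_deg = sample(rotations, practicing_per_type, replace = TRUE),
      task = task_pr, stringsAsFactors = FALSE)

    n_rot <- if (grepl("-target$", ty)) 1L else 3L
    rot <- unlist(lapply(seq_len(nrow(te)), function(i)
      sample(rotations, n_rot)), use.names = FALSE)
    tt <- data.frame(
      patch_id = rep(te$patch_id, each = n_rot), type_label = ty,
      is_target = grepl("-target$", ty), complexity = sub("-.*", "", ty),
      rotation_deg = rot, stringsAsFactors = FALSE)
    n <- nrow(tt)
    if (n %% (2L * n_sessions) != 0)
      stop(sprintf("type %s: %d testing trials do not split over %d tasks x %d sessions",
                   ty, n, 2L, n_sessions))
    ord <- sample(n)
    tt <- tt[ord, ]
    tt$task <- rep(c("single", "dual"), each = n / 2)
    tt$session <- rep(rep(seq_len(n_sessions), each = n / (2 * n_sessions)), 2)
    testing[[ty]] <- tt
  }
  practicing <- do.call(rbind, practicing)
  practicing <- practicing[sample(nrow(practicing)), ]
  practicing$block <- "practice"
  testing <- do.call(rbind, testing)

  out <- list()
  for (s in seq_len(n_sessions)) {
    for (task in c("single", "dual")) {
      tr <- testing[testing$session == s & testing$task == task, ]
      nb <- if (task == "single") n_single_blocks else n_dual_blocks
      if (nrow(tr) %% nb != 0)
        stop(sprintf("session %d %s-task: %d trials do not fill %d equal blocks",
                     s, task, nrow(tr), nb))
      tr <- tr[sample(nrow(tr)), ]
      tr$block <- rep(seq_len(nb), each = nrow(tr) / nb)
      tr$question <- FALSE
      if (task == "dual") {
        q_per_type <- nrow(tr) / (3L * length(types))
        if (q_per_type != round(q_per_type))
          stop("one third of dual-task trials does not split evenly over types")
        for (ty in types) {
          idx <- which(tr$type_label == ty)
          tr$question[sample(idx, q_per_type)] <- TRUE
        }
      }
      out[[paste(s, task)]] <- tr
    }
  }
  testing <- do.call(rbind, out)
  testing <- testing[order(testing$session, testing$task, testing$block), ]
  testing$trial <- stats::ave(seq_len(nrow(testing)),
                              paste(testing$session, testing$task, testing$block),
                              FUN = seq_along)
  rownames(testing) <- rownames(practicing) <- NULL

  structure(list(
    practicing = practicing, testing = testing,
    counts = list(
      n_target = sum(testing$is_target),
      n_nontarget = sum(!testing$is_target),
      practicing_per_task = table(practicing$task),
      block_sizes = table(paste(testing$task, testing$block)),
      questions_per_type_session = with(testing[testing$question, ],
                                        table(type_label, session)))),
    class = "stimulus_set")
}

#' @export
print.stimulus_set <- function(x, ...) {
  cat("<stimulus_set>\n")
  cat(sprintf("  practicing: %d trials (%s)\n", nrow(x$practicing),
              paste(names(x$counts$practicing_per_task),
                    x$counts$practicing_per_task, sep = "=", collapse = ", ")))
  cat(sprintf("  testing: %d trials (%d target : %d non-target)\n",
              nrow(x$testing), x$counts$n_target, x$counts$n_nontarget))
  invisible(x)
}
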