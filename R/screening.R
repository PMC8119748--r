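#' Stimulus complexity, brightness and size scores
#'
#' Quantitative screening scores for candidate stimulus patches:
#' * `score_entropy()`: Shannon information entropy (bits) of the 256-bin
#'   gray-level histogram, zero-probability bins skipped. RGB input is
#'   converted to gray as `round(0.299 R + 0.587 G + 0.114 B)`.
#' * `score_uniformity()`: gray-level uniformity index, the mean over
#'   non-overlapping `block` x `block` tiles of the within-tile gray-level
#'   (population) standard deviation; larger values mean more heterogeneous
#'   texture.
#' * `score_brightness()`: mean of the HSI intensity channel,
#'   `(R + G + B) / (3 * 255)`, in `[0, 1]`.
#' * `score_vehicle_size()`: absolute shoelace area (pixel^2) of the 4-point
#'   vehicle location quadrilateral, invariant to vertex winding.
#'
#' @param image For `score_entropy`/`score_uniformity`: an 8-bit grayscale
#'   matrix (0-255) or an RGB array (converted internally). For
#'   `score_brightness`: an 8-bit RGB array.
#' @return A single numeric score.
#' @examples
#' score_entropy(matrix(128, 8, 8))          # 0 bits
#' score_brightness(array(255L, c(4, 4, 3))) # 1
#' @export
score_entropy <- function(image) {
  g <- .to_gray(image)
  if (length(g) == 0) stop("empty image")
  p <- tabulate(g + 1L, nbins = 256L) / length(g)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' @rdname score_entropy
#' @param block Tile side length in pixels; image dimensions must be
#'   divisible by it.
#' @export
score_uniformity <- function(image, block = 16L) {
  g <- .to_gray(image)
  d <- dim(g)
  if (any(d %% block != 0))
    stop("image dimensions must be divisible by the block size")
  ti <- (seq_len(d[1]) - 1L) %/% block
  tj <- (seq_len(d[2]) - 1L) %/% block
  tile <- outer(ti, tj * (d[1] %/% block), "+")
  vals <- as.numeric(g)
  n <- block * block
  mu <- tapply(vals, tile, mean)
  m2 <- tapply(vals^2, tile, mean)
  mean(sqrt(pmax(m2 - mu^2, 0)))
}

#' @rdname score_entropy
#' @export
score_brightness <- function(image) {
  stopifnot(length(dim(image)) == 3, dim(image)[3] >= 3)
  mean(image[, , 1] + image[, , 2] + image[, , 3]) / (3 * 255)
}

#' @rdname score_entropy
#' @param quad 4 x 2 matrix of quadrilateral vertex coordinates (pixels).
#' @export
score_vehicle_size <- function(quad) {
  stopifnot(is.matrix(quad), nrow(quad) == 4, ncol(quad) == 2)
  x <- quad[, 1]; y <- quad[, 2]
  a <- 0.5 * abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y))
  if (a == 0) stop("degenerate quadrilateral: zero area")
  a
}

.to_gray <- function(image) {
  if (length(dim(image)) == 3) {
    g <- round(0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3])
  } else {
    g <- image
  }
  storage.mode(g) <- "integer"
  g
}

#' Score a set of stimulus patches
#'
#' Fills the `scores` field of each patch and returns a per-patch score
#' table.
#'
#' @param patches List of `stimulus_patch` objects.
#' @return A data.frame: `patch_id`, `type_label`, `scene`, `is_target`,
#'   `entropy`, `uniformity`, `brightness`, `vehicle_size` (`NA` for
#'   non-targets).
#' @export
score_patches <- function(patches) {
  rows <- lapply(seq_along(patches), function(i) {
    p <- patches[[i]]
    data.frame(
      patch_id = p$patch_id %||% sprintf("patch_%04d", i),
      type_label = p$type_label,
      scene = sub("-.*", "", p$type_label),
      is_target = grepl("-target$", p$type_label),
      entropy = score_entropy(p$image),
      uniformity = score_uniformity(p$image),
      brightness = score_brightness(p$image),
      vehicle_size = if (is.null(p$quad)) NA_real_ else score_vehicle_size(p$quad),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Iterative interquartile-range outlier screening
#'
#' Repeatedly removes patches whose scores fall outside
#' `[Q1 - k IQR, Q3 + k IQR]` on each measure in a fixed order (entropy,
#' uniformity, brightness, then vehicle size over target patches only),
#' recomputing quartiles from the currently kept set after every removal
#' step, until a full pass removes nothing. Quartiles use the
#' linear-interpolation convention (R type 7); values exactly on a fence are
#' kept.
#'
#' @param scores Score table as returned by [score_patches()].
#' @param k Fence factor (default 1.5).
#' @param measures Screening order; size is always restricted to targets.
#' @return List with `kept` and `removed` score tables (removed rows carry
#'   `removal_pass` and `removal_measure`) and `n_passes`.
#' @export
iterative_iqr_screen <- function(scores, k = 1.5,
                                 measures = c("entropy", "uniformity",
                                              "brightness", "vehicle_size")) {
  stopifnot(is.data.frame(scores), nrow(scores) >= 4)
  kept <- scores
  removed <- scores[0, ]
  removed$removal_pass <- integer(0)
  removed$removal_measure <- character(0)
  pass <- 0L
  repeat {
    pass <- pass + 1L
    changed <- FALSE
    for (m in measures) {
      v <- kept[[m]]
      idx <- if (m == "vehicle_size") which(kept$is_target & !is.na(v)) else seq_len(nrow(kept))
      x <- v[idx]
      if (length(x) < 4) next
      q <- stats::quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
      iqr <- q[2] - q[1]
      out <- idx[x < q[1] - k * iqr | x > q[2] + k * iqr]
      if (length(out)) {
        changed <- TRUE
        gone <- kept[out, ]
        gone$removal_pass <- pass
        gone$removal_measure <- m
        removed <- rbind(removed, gone)
        kept <- kept[-out, ]
        if (nrow(kept) < 4)
          stop("fewer than 4 patches remain during IQR screening; ",
               "inputs are too heterogeneous for fence estimation")
      }
    }
    if (!changed) break
  }
  rownames(kept) <- rownames(removed) <- NULL
  list(kept = kept, removed = removed, n_passes = pass)
}

#' Balance per-type counts by seeded downsampling
#'
#' Downsamples every stimulus type in the kept score table to the minimum
#' per-type count by uniform sampling without replacement.
#'
#' @param kept Kept score table (must contain `type_label`).
#' @param seed Integer seed for the selection.
#' @param n Optional target count per type (must not exceed the minimum
#'   per-type count); default is the minimum count itself.
#' @return The balanced score table (equal `type_label` counts).
#' @export
balance_types <- function(kept, seed = 1L, n = NULL) {
  counts <- table(kept$type_label)
  if (any(counts == 0) || length(counts) == 0) stop("a stimulus type is empty")
  if (is.null(n)) n <- min(counts)
  if (n > min(counts)) stop("requested per-type count exceeds the minimum available")
  set.seed(as.integer(seed))
  idx <- unlist(lapply(split(seq_len(nrow(kept)), kept$type_label),
                       function(i) sort(sample(i, n))), use.names = FALSE)
  out <- kept[sort(idx), ]
  rownames(out) <- NULL
  out
}
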