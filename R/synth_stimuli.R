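#' Generate one synthetic aerial-style stimulus patch
#'
#' Draws a 240 x 240 8-bit RGB texture whose histogram entropy and gray-level
#' uniformity separate the two complexity levels in expectation: simple
#' scenes are smooth large-scale textures with a narrow gray histogram,
#' complex scenes add fine-grained high-contrast structure. Mean brightness
#' and (for targets) vehicle size are drawn from common distributions across
#' complexity levels, so only the complexity scores differ systematically.
#' When `with_vehicle`, a small high-contrast rectangular object is
#' composited and its 4-corner location quadrilateral recorded (0-based
#' pixel coordinates, origin top-left).
#'
#' @param complexity_level `"simple"` or `"complex"`.
#' @param with_vehicle Logical; composite a vehicle-like object.
#' @param seed Integer seed; identical calls are pixel-identical.
#' @param size Patch side length in pixels.
#' @return A `stimulus_patch`: list with `image` (size x size x 3 integer
#'   array, 0-255), `type_label`, `quad` (4 x 2 matrix or `NULL`), `scores`
#'   (`NULL` until scored).
#' @examples
#' p <- generate_stimulus_image("simple", FALSE, seed = 1)
#' dim(p$image)
#' @export
generate_stimulus_image <- function(complexity_level = c("simple", "complex"),
                                    with_vehicle = FALSE, seed = 1L,
                                    size = 240L) {
  complexity_level <- match.arg(complexity_level)
  set.seed(as.integer(seed))
  base <- min(max(stats::rnorm(1, 0.44, 0.05), 0.2), 0.7)

  coarse <- .bilinear_field(12L, size, sd = 0.055)
  gray <- base + coarse
  if (complexity_level == "complex") {
    mid <- .bilinear_field(40L, size, sd = 0.10)
    fine <- matrix(stats::rnorm(size * size, 0, 0.055), size, size)
    gray <- gray + mid + fine
  } else {
    fine <- matrix(stats::rnorm(size * size, 0, 0.012), size, size)
    gray <- gray + fine
  }
  gray <- pmin(pmax(gray, 0), 1)

  # faint independent color tint, common to both levels
  img <- array(0, c(size, size, 3))
  for (ch in 1:3)
    img[, , ch] <- pmin(pmax(gray + stats::rnorm(1, 0, 0.015), 0), 1)

  quad <- NULL
  if (isTRUE(with_vehicle)) {
    area <- max(stats::rnorm(1, 640, 44), 200)
    ar <- stats::runif(1, 1.6, 2.4)
    w <- max(4L, as.integer(round(sqrt(area * ar))))
    h <- max(4L, as.integer(round(area / w)))
    x0 <- sample.int(size - w - 40L, 1) + 20L
    y0 <- sample.int(size - h - 40L, 1) + 20L
    dark <- stats::runif(1) < 0.5
    col <- if (dark) stats::runif(1, 0.02, 0.12) else stats::runif(1, 0.85, 0.98)
    rows <- y0:(y0 + h - 1L); cols <- x0:(x0 + w - 1L)
    for (ch in 1:3) img[rows, cols, ch] <- col
    # 0-based bounding quadrilateral, counter-clockwise from top-left
    quad <- matrix(c(x0 - 1L, y0 - 1L,
                     x0 - 1L + w, y0 - 1L,
                     x0 - 1L + w, y0 - 1L + h,
                     x0 - 1L, y0 - 1L + h),
                   ncol = 2, byrow = TRUE,
                   dimnames = list(NULL, c("x", "y")))
  }

  label <- paste0(complexity_level, "-", if (with_vehicle) "target" else "nontarget")
  structure(list(image = array(as.integer(round(img * 255)), dim(img)),
                 type_label = label, quad = quad, scores = NULL),
            class = "stimulus_patch")
}

# smooth random field: k x k normal grid, bilinear-interpolated to n x n
.bilinear_field <- function(k, n, sd) {
  g <- matrix(stats::rnorm(k * k, 0, sd), k, k)
  xs <- seq(1, k, length.out = n)
  i0 <- pmin(floor(xs), k - 1L); f <- xs - i0
  rows <- g[i0, , drop = FALSE] * (1 - f) + g[i0 + 1L, , drop = FALSE] * f
  rows[, i0, drop = FALSE] * rep(1 - f, each = n) +
    rows[, i0 + 1L, drop = FALSE] * rep(f, each = n)
}

#' Generate a batch of labeled stimulus patches
#'
#' Convenience wrapper producing `n_per_type` patches of each of the four
#' stimulus types (simple/complex x target/nontarget) with per-patch seeds
#' derived from `seed`.
#'
#' @param n_per_type Patches per type.
#' @param seed Master seed.
#' @return List of `stimulus_patch` objects with a `patch_id` field added.
#' @export
generate_stimulus_set <- function(n_per_type = 20L, seed = 1L) {
  types <- expand.grid(scene = c("simple", "complex"),
                       vehicle = c(TRUE, FALSE), stringsAsFactors = FALSE)
  out <- vector("list", 4L * n_per_type)
  k <- 0L
  for (r in seq_len(nrow(types))) {
    for (i in seq_len(n_per_type)) {
      k <- k + 1L
      p <- generate_stimulus_image(types$scene[r], types$vehicle[r],
                                   seed = sub_seed(seed, "stimuli", k))
      p$patch_id <- sprintf("%s_%03d", p$type_label, i)
      out[[k]] <- p
    }
  }
  out
}

#' Write / read a stimulus patch as PNG with a quadrilateral sidecar row
#'
#' @param patch A `stimulus_patch`.
#' @param path PNG file path.
#' @return `write_patch_png` invisibly returns the sidecar row (a one-row
#'   data.frame with the patch id, type and flattened quad coordinates, or
#'   NAs when no vehicle); `read_patch_png` the reconstructed patch.
#' @export
write_patch_png <- function(patch, path) {
  img <- aperm(patch$image, c(1, 2, 3)) / 255
  png::writePNG(img, path)
  q <- if (is.null(patch$quad)) rep(NA_real_, 8) else as.numeric(t(patch$quad))
  invisible(data.frame(patch_id = patch$patch_id %||% basename(path),
                       type_label = patch$type_label,
                       x1 = q[1], y1 = q[2], x2 = q[3], y2 = q[4],
                       x3 = q[5], y3 = q[6], x4 = q[7], y4 = q[8]))
}

#' @rdname write_patch_png
#' @param sidecar One row of the sidecar table for this patch, or `NULL`.
#' @export
read_patch_png <- function(path, sidecar = NULL) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  quad <- NULL; label <- "moderate"; id <- basename(path)
  if (!is.null(sidecar)) {
    label <- sidecar$type_label
    id <- sidecar$patch_id
    if (!is.na(sidecar$x1))
      quad <- matrix(as.numeric(sidecar[paste0(c("x", "y"), rep(1:4, each = 2))]),
                     ncol = 2, byrow = TRUE, dimnames = list(NULL, c("x", "y")))
  }
  structure(list(image = array(as.integer(round(img[, , 1:3] * 255)), c(dim(img)[1:2], 3)),
                 type_label = label, quad = quad, scores = NULL, patch_id = id),
            class = "stimulus_patch")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.stimulus_patch <- function(x, ...) {
  cat(sprintf("<stimulus_patch> %s %dx%d %s%s\n",
              x$patch_id %||% "", dim(x$image)[1], dim(x$image)[2], x$type_label,
              if (is.null(x$quad)) "" else " (vehicle quad recorded)"))
  invisible(x)
}
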