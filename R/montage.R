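#' Standard 63-channel 10-10 montage
#'
#' Channel labels of the 63 scalp EEG electrodes used throughout the package,
#' a subset of the international 10-10 system as laid out by a 64-channel
#' actiCAP-style cap recorded against a separate Iz reference.
#'
#' @return Character vector of 63 unique channel labels.
#' @export
montage_1010 <- function() {
  c("Fp1", "Fpz", "Fp2",
    "AF7", "AF3", "AFz", "AF4", "AF8",
    "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8",
    "FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8",
    "T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8",
    "TP9", "TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8", "TP10",
    "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8",
    "PO7", "PO3", "POz", "PO4", "PO8",
    "O1", "Oz", "O2")
}

#' Electrode cluster definitions
#'
#' The two analysis clusters: six occipital electrodes carrying the late
#' occipital positivity (LOP) and five central centro-parietal electrodes
#' carrying the centro-parietal positivity (CPP).
#'
#' @param name `"occipital"` or `"centro-parietal"`.
#' @return A list with elements `name` and `channels`, class `cluster_spec`.
#' @examples
#' cluster_spec("occipital")$channels
#' @export
cluster_spec <- function(name = c("occipital", "centro-parietal")) {
  name <- match.arg(name)
  channels <- switch(name,
    "occipital" = c("O1", "O2", "PO3", "PO4", "PO7", "PO8"),
    "centro-parietal" = c("Cz", "CPz", "Pz", "CP1", "CP2"))
  structure(list(name = name, channels = channels), class = "cluster_spec")
}

#' The 2 x 2 x 2 experimental bin space
#'
#' Every epoch belongs to one cell of target presence (target / nontarget)
#' x scene complexity (simple / complex) x task (single / dual).
#'
#' @return A data.frame with columns `bin`, `is_target`, `scene`, `task`,
#'   one row per bin, in a fixed order.
#' @export
condition_bins <- function() {
  g <- expand.grid(
    target = c("target", "nontarget"),
    scene = c("simple", "complex"),
    task = c("single", "dual"),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  data.frame(
    bin = paste(g$target, g$scene, g$task, sep = "_"),
    is_target = g$target == "target",
    scene = g$scene,
    task = g$task,
    stringsAsFactors = FALSE)
}

#' @export
print.cluster_spec <- function(x, ...) {
  cat(sprintf("<cluster_spec> %s: %s\n", x$name,
              paste(x$channels, collapse = ", ")))
  invisible(x)
}
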