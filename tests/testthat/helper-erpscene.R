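# Shared fixtures built in code.

# Reduced montage covering both analysis clusters plus frontal sites for
# blink artifacts; keeps unit-test sessions cheap.
small_montage <- function() {
  c("Fp1", "Fpz", "Fp2", "Fz", "Cz", "C1", "C2", "CPz", "CP1", "CP2",
    "Pz", "P1", "P2", "POz", "PO3", "PO4", "PO7", "PO8", "O1", "Oz", "O2")
}

small_cfg <- function(n_participants = 2, n_trials_per_bin = 6, ...) {
  synth_config(n_participants = n_participants,
               n_trials_per_bin = n_trials_per_bin,
               montage = small_montage(), ...)
}

zero_noise_cfg <- function(...) {
  cfg <- small_cfg(noise = list(pink_sd = 0, white_sd = 0, pink_exponent = 1),
                   artifact_rate = 0, ...)
  cfg$lop_params$participant_latency_sd_ms <- 0
  cfg$lop_params$participant_amplitude_sd_uv <- 0
  cfg$cpp_params$participant_latency_sd_ms <- 0
  cfg$cpp_params$participant_amplitude_sd_uv <- 0
  cfg
}

# Assemble an eeg_epochs object directly from a trials x channels x time
# array (bypasses the continuous pipeline for statistics unit tests).
make_epochs <- function(arr, bins, correct = rep(TRUE, dim(arr)[1]),
                        channels = paste0("ch", seq_len(dim(arr)[2])),
                        time_ms = seq(-200, by = 4, length.out = dim(arr)[3])) {
  structure(list(data = arr, time_ms = time_ms, channels = channels,
                 rate = 250,
                 events = data.frame(onset_sample = seq_len(dim(arr)[1]),
                                     bin = bins, correct = correct),
                 rejected = rep(FALSE, dim(arr)[1]),
                 reject_reason = rep(NA_character_, dim(arr)[1]),
                 dropped = NULL),
            class = "eeg_epochs")
}

# Independent Benjamini-Hochberg step-up oracle (brute force).
bh_reject_bruteforce <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  below <- which(ps <= q * seq_len(m) / m)
  rej <- logical(m)
  if (length(below)) rej[o[seq_len(max(below))]] <- TRUE
  rej
}

# Independent per-point pooled t-test oracle via stats::t.test.
pointwise_t_bruteforce <- function(A, B) {
  vapply(seq_len(ncol(A)), function(j) {
    tt <- stats::t.test(A[, j], B[, j], var.equal = TRUE)
    c(t = unname(tt$statistic), p = tt$p.value)
  }, c(t = 0, p = 0))
}

# Closed-form zero-phase Butterworth band-pass magnitude response applied in
# the frequency domain: the filtering oracle, independent of the
# signal-package path used by resample_filter(). The 50 Hz notch is omitted:
# its response is ~1 over the sub-30 Hz band the ERP kernels occupy.
apply_bandpass_oracle <- function(x, rate, band = c(0.5, 100)) {
  n <- length(x)
  nfft <- stats::nextn(2 * n, 2)
  f <- pmin(0:(nfft - 1), nfft - 0:(nfft - 1)) * rate / nfft
  # |H|^2 of the order-4 band-pass ~ HP(4, lo) * LP(4, hi) magnitudes squared
  hp <- (f / band[1])^8 / (1 + (f / band[1])^8)
  lp <- 1 / (1 + (f / band[2])^8)
  X <- stats::fft(c(x, rep(0, nfft - n)))
  Re(stats::fft(X * hp * lp, inverse = TRUE))[seq_len(n)] / nfft
}
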