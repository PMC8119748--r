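toy_eeg <- function(x, n_ch = 3, rate = 1000) {
  eeg_continuous(matrix(rep(x, each = n_ch), n_ch, length(x),
                        dimnames = list(paste0("ch", 1:n_ch), NULL)),
                 rate, paste0("ch", 1:n_ch), "Iz")
}

test_that("resample_filter notches 50 Hz, removes DC and preserves the passband", {
  rate <- 1000; t <- (0:19999) / rate
  mid <- 1500:3000  # away from edges

  f50 <- resample_filter(toy_eeg(10 * sin(2 * pi * 50 * t)))
  expect_equal(f50$rate, 250)
  expect_lt(sd(f50$data[1, mid]), 0.05 * 10 / sqrt(2))

  fdc <- resample_filter(toy_eeg(rep(10, 20000)))
  expect_lt(abs(mean(fdc$data[1, mid])), 0.01)

  f10 <- resample_filter(toy_eeg(10 * sin(2 * pi * 10 * t)))
  expect_equal(sd(f10$data[1, mid]), 10 / sqrt(2), tolerance = 0.05)

  expect_error(resample_filter(toy_eeg(rep(0, 100)), band = c(0.5, 130)),
               "Nyquist")
  expect_error(resample_filter(toy_eeg(rep(0, 100)), target_rate = 300),
               "divide")
})

test_that("filtering is zero-phase: an impulse stays centered", {
  x <- rep(0, 20000); x[8001] <- 100
  out <- resample_filter(toy_eeg(x))
  expect_equal(which.max(abs(out$data[1, ])), 8000 / 4 + 1)
})

test_that("average re-reference zeroes the channel mean and is idempotent", {
  set.seed(1)
  raw <- eeg_continuous(matrix(rnorm(5 * 100, 3), 5, 100), 250,
                        paste0("c", 1:5), "Iz")
  ref <- rereference_average(raw)
  expect_lt(max(abs(colMeans(ref$data))), 1e-12)
  expect_equal(rereference_average(ref)$data, ref$data, tolerance = 1e-12)
  two <- eeg_continuous(matrix(c(1, 3), 2, 10), 250, c("a", "b"), "Iz")
  expect_equal(rereference_average(two)$data,
               matrix(c(-1, 1), 2, 10), ignore_attr = TRUE)
})

test_that("epoching subtracts the pre-stimulus baseline exactly", {
  rate <- 250
  n <- 5000
  events <- data.frame(onset_sample = c(500, 1500, 4950),
                       bin = "target_simple_single", correct = TRUE)
  # constant channel -> all-zero epochs
  const <- eeg_continuous(matrix(7, 2, n), rate, c("a", "b"), "Iz")
  ep <- epoch_and_baseline(const, events)
  expect_equal(dim(ep$data), c(2, 2, 300))  # third event too close to the edge
  expect_equal(ep$dropped$onset_sample, 4950)
  expect_lt(max(abs(ep$data)), 1e-12)
  expect_equal(ep$time_ms, seq(-200, 996, by = 4))

  # ramp v(t) = t: epoch = t - mean(t over [-200, 0))
  ramp <- eeg_continuous(matrix(seq_len(n), 1, n, byrow = TRUE), rate, "a", "Iz")
  ep2 <- epoch_and_baseline(ramp, events[1, ])
  rel <- seq(-50, 249)
  expected <- (500 + rel) - mean(500 + rel[rel < 0])
  expect_equal(ep2$data[1, 1, ], expected, tolerance = 1e-12)
  # baseline window mean is zero for every retained epoch and channel
  base <- ep2$time_ms < 0
  expect_lt(abs(mean(ep2$data[1, 1, base])), 1e-9)
})

test_that("joint-probability rejection flags spikes but spares homogeneous data", {
  set.seed(7)
  arr <- array(rnorm(60 * 4 * 300), c(60, 4, 300))
  ep <- make_epochs(arr, rep(condition_bins()$bin, length.out = 60))
  out <- reject_improbable(ep)
  expect_lt(mean(out$rejected), 0.10)

  spiky <- arr
  spiky[13, 2, 40:60] <- 500
  out2 <- reject_improbable(make_epochs(spiky, ep$events$bin))
  expect_true(out2$rejected[13])
  expect_match(out2$reject_reason[13], "single|global")

  out3 <- reject_improbable(ep, single_sd = Inf, global_sd = Inf)
  expect_equal(sum(out3$rejected), 0)

  flat <- array(1, c(12, 2, 50))
  expect_warning(out4 <- reject_improbable(make_epochs(flat,
                   rep("target_simple_single", 12))), "degenerate")
  expect_equal(sum(out4$rejected), 0)
})

test_that("zero-noise sessions pass rejection untouched", {
  cfg <- zero_noise_cfg(n_trials_per_bin = 2, seed = 5)
  ep <- preprocess_session(generate_session(cfg, 1))
  expect_equal(sum(ep$rejected), 0)
})

test_that("strong blink artifacts are detected at the configured rate", {
  # probability-based rejection relies on artifacts being rare; at the
  # default 5% rate the frontal blinks are reliably improbable
  cfg <- small_cfg(n_participants = 3, n_trials_per_bin = 10,
                   artifact_rate = 0.05, seed = 77)
  hits <- n_art <- 0
  for (i in 1:3) {
    ses <- generate_session(cfg, i)
    ep <- preprocess_session(ses)
    hits <- hits + sum(ep$rejected[ses$artifact_trials])
    n_art <- n_art + length(ses$artifact_trials)
  }
  expect_gt(n_art, 0)
  expect_gte(hits / n_art, 0.8)
})

test_that("the pipeline returns the injected kernel up to the documented filter response", {
  cfg <- zero_noise_cfg(n_trials_per_bin = 2, seed = 5)
  ses <- generate_session(cfg, 1)
  ep <- preprocess_session(ses)
  tm <- ep$time_ms
  for (cl_name in c("centro-parietal", "occipital")) {
    cl <- cluster_spec(cl_name)
    erp <- bin_average(ep, cl)
    for (b in c("target_simple_single", "nontarget_complex_dual")) {
      kern <- generate_erp_kernel("LOP",
                list(latency_ms = cfg$lop_params$latency_ms[[b]],
                     amplitude_uv = cfg$lop_params$amplitude_uv[[b]],
                     width_ms = cfg$lop_params$width_ms), cfg$montage,
                t_ms = 0:1000) +
              generate_erp_kernel("CPP",
                list(latency_ms = cfg$cpp_params$latency_ms[[b]],
                     amplitude_uv = cfg$cpp_params$amplitude_uv[[b]],
                     width_ms = cfg$cpp_params$width_ms), cfg$montage,
                t_ms = 0:1000)
      # oracle: closed-form zero-phase filter response + average reference,
      # sampled on the epoch axis, baseline-corrected
      padded <- cbind(matrix(0, nrow(kern), 1000), kern,
                      matrix(0, nrow(kern), 1000))
      filt <- t(apply(padded, 1, apply_bandpass_oracle, rate = 1000))
      filt <- sweep(filt, 2, colMeans(filt))
      cols <- 1001 + tm  # kernel t=0 at column 1001, 1 ms steps
      series <- colMeans(filt[cl$channels, cols])
      series <- series - mean(series[tm < 0])
      win <- if (cl_name == "occipital") tm >= 250 & tm <= 450 else tm >= 400 & tm <= 650
      peak <- max(abs(series))
      expect_lt(max(abs(erp$waveforms[[b]] - series)[win]), 0.05 * peak)
    }
  }
})
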