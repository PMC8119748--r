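test_that("bin_average reduces identical and opposite trials correctly", {
  s <- sin(seq(0, 4 * pi, length.out = 300))
  arr <- array(0, c(4, 3, 300))
  for (i in 1:4) for (c in 1:3) arr[i, c, ] <- s
  ep <- make_epochs(arr, rep("target_simple_single", 4),
                    channels = c("Cz", "CPz", "Pz"))
  # pad channel set so the cluster is present
  ep$channels <- c("Cz", "CPz", "Pz")
  cl <- structure(list(name = "centro-parietal", channels = c("Cz", "CPz", "Pz")),
                  class = "cluster_spec")
  out <- bin_average(ep, cl)
  expect_equal(out$waveforms[["target_simple_single"]], s)
  expect_equal(out$n_trials[["target_simple_single"]], 4)

  arr2 <- arr
  arr2[c(2, 4), , ] <- -arr2[c(2, 4), , ]
  out2 <- bin_average(make_epochs(arr2, rep("b", 4), channels = cl$channels), cl)
  expect_equal(out2$waveforms[["b"]], rep(0, 300))
})

test_that("bin_average uses only retained, correct trials", {
  arr <- array(1, c(4, 2, 10))
  arr[2, , ] <- 100  # incorrect trial
  arr[3, , ] <- 100  # rejected trial
  ep <- make_epochs(arr, rep("b", 4),
                    correct = c(TRUE, FALSE, TRUE, TRUE),
                    channels = c("Cz", "Pz"))
  ep$rejected[3] <- TRUE
  cl <- structure(list(name = "x", channels = c("Cz", "Pz")),
                  class = "cluster_spec")
  out <- bin_average(ep, cl)
  expect_equal(unname(out$waveforms[["b"]]), rep(1, 10))
  expect_equal(out$n_trials[["b"]], 2)
})

test_that("pointwise t/BH matches a brute-force oracle exactly on toys", {
  set.seed(11)
  A <- matrix(rnorm(5 * 10), 5, 10)
  B <- matrix(rnorm(5 * 10, 0.8), 5, 10)
  tr <- pointwise_fdr_ttest(A, B, time_ms = seq(0, 36, by = 4), q = 0.05)
  oracle <- pointwise_t_bruteforce(A, B)
  expect_equal(tr$t, unname(oracle["t", ]), tolerance = 1e-12)
  expect_equal(tr$p, unname(oracle["p", ]), tolerance = 1e-12)
  expect_identical(tr$significant, bh_reject_bruteforce(tr$p, 0.05))
  expect_equal(tr$df, 8)
})

test_that("t trace is symmetric under group exchange and null under equality", {
  set.seed(2)
  A <- matrix(rnorm(6 * 50), 6, 50)
  tms <- seq(0, by = 4, length.out = 50)
  same <- pointwise_fdr_ttest(A, A, tms)
  expect_equal(sum(same$significant), 0)
  expect_true(all(same$p == 1))  # pooled SD > 0 but means equal -> t = 0
  B <- matrix(rnorm(6 * 50, 0.3), 6, 50)
  ab <- pointwise_fdr_ttest(A, B, tms)
  ba <- pointwise_fdr_ttest(B, A, tms)
  expect_equal(ab$t, -ba$t)
  expect_identical(ab$significant, ba$significant)
})

test_that("a confined amplitude step yields a confined significant interval", {
  set.seed(1)
  tms <- seq(-200, 996, by = 4)
  step <- as.numeric(tms >= 400 & tms <= 500) * 2
  A <- t(replicate(24, step + 0.3 * rnorm(length(tms))))
  B <- t(replicate(24, 0.3 * rnorm(length(tms))))
  tr <- pointwise_fdr_ttest(A, B, tms)
  sig_t <- tms[tr$significant]
  expect_true(all(sig_t >= 400 & sig_t <= 500))
  expect_gte(length(sig_t) / sum(tms >= 400 & tms <= 500), 0.8)
})

test_that("peak measures honor windows and the earliest-tie rule", {
  tms <- seq(-200, 996, by = 4)
  bump <- 5 * exp(-(tms - 520)^2 / (2 * 60^2))
  pm <- peak_measure(bump, tms, "CPP")
  expect_equal(pm$latency_ms, 520)
  expect_equal(pm$amplitude, max(bump))

  flat <- rep(0, length(tms))
  pm0 <- peak_measure(flat, tms, "CPP")
  expect_equal(pm0$latency_ms, 400)  # window start on total tie
  expect_equal(pm0$amplitude, 0)

  two <- rep(0, length(tms)); two[tms == 448] <- 3; two[tms == 600] <- 3
  expect_equal(peak_measure(two, tms, "CPP")$latency_ms, 448)

  expect_error(peak_measure(bump, tms, "CPP", window = c(400, 2000)), "window")
})

test_that("jackknife test handles degenerate and shifted groups as specified", {
  tms <- seq(-200, 996, by = 4)
  base <- 5 * exp(-(tms - 500)^2 / (2 * 60^2))
  A <- rbind(base, base, base, base)
  jk0 <- jackknife_latency_test(A, A, tms, "CPP")
  expect_equal(jk0$t, 0)
  expect_equal(jk0$p, 1)

  shift <- 5 * exp(-(tms - 560)^2 / (2 * 60^2))
  B <- rbind(shift, shift, shift, shift)
  jk <- jackknife_latency_test(B, A, tms, "CPP")
  expect_equal(jk$difference, 60)
  expect_true(jk$se_zero)
  expect_lt(jk$p, 1e-300)
})

test_that("for linear statistics the jackknife SE equals the ordinary SE", {
  set.seed(9)
  A <- matrix(rnorm(7 * 40), 7, 40)
  B <- matrix(rnorm(9 * 40, 0.5), 9, 40)
  tms <- seq(0, by = 4, length.out = 40)
  jk <- jackknife_latency_test(A, B, tms,
                               statistic = function(s, t) mean(s))
  # closed form: leave-one-out jackknife of a mean collapses to s^2/n
  se_ref <- sqrt(var(rowMeans(A)) / nrow(A) + var(rowMeans(B)) / nrow(B))
  expect_equal(jk$se, se_ref, tolerance = 1e-9)
  expect_equal(jk$difference, mean(rowMeans(A)) - mean(rowMeans(B)),
               tolerance = 1e-12)
})

test_that("simulated scene contrast is detected by the jackknife test", {
  cfg <- synth_config(seed = 3)
  cl <- cluster_spec("centro-parietal")
  A <- simulate_participant_waveforms(cfg, "target_simple_single", cl, 24, seed = 301)
  B <- simulate_participant_waveforms(cfg, "target_complex_single", cl, 24, seed = 302)
  tms <- seq(-200, 996, by = 4)
  jk <- jackknife_latency_test(A, B, tms, "CPP")
  expect_lt(jk$p, 0.001)
  expect_lt(jk$difference, 0)  # simple peaks earlier
  expect_equal(abs(jk$difference), 88, tolerance = 30)
})

test_that("performance splits take the metric extremes deterministically", {
  set.seed(1)
  perf <- data.frame(participant = sprintf("P%02d", 1:48),
                     value = runif(48, 0.5, 1.2))
  sp <- split_by_performance(perf, "detection_rt", k = 16)
  expect_length(sp$high, 16)
  expect_length(intersect(sp$high, sp$low), 0)
  expect_true(max(perf$value[perf$participant %in% sp$high]) <
                min(perf$value[perf$participant %in% sp$low]))
  sp12 <- split_by_performance(perf, "detection_rt", k = 12)
  expect_length(sp12$high, 12)

  acc <- data.frame(participant = sprintf("P%02d", 1:40),
                    value = rep(0.8, 40))
  spc <- split_by_performance(acc, "similarity_accuracy", k = 16)
  expect_identical(spc$low, sprintf("P%02d", 1:16))     # tie rule: by id
  expect_identical(spc$high, sprintf("P%02d", 25:40))
  expect_error(split_by_performance(acc[1:20, ], "similarity_accuracy", 16),
               "nrow")
})
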