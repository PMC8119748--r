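#' Spatial weight profile of a simulated ERP component
#'
#' LOP weight is 1 on the six occipital cluster electrodes with a small
#' spill-over onto their neighbors; CPP weight is 1 on the five central
#' centro-parietal electrodes likewise. The two profiles are disjoint on the
#' opposite cluster's electrodes, so cluster means measure one component
#' each.
#'
#' @param component `"LOP"` or `"CPP"`.
#' @param montage Channel label vector.
#' @return Named numeric weight per channel.
#' @export
component_weights <- function(component, montage = montage_1010()) {
  w <- stats::setNames(numeric(length(montage)), montage)
  if (component == "LOP") {
    w[intersect(cluster_spec("occipital")$channels, montage)] <- 1
    w[intersect(c("POz", "Oz", "P7", "P8", "P5", "P6"), montage)] <- 0.3
  } else if (component == "CPP") {
    w[intersect(cluster_spec("centro-parietal")$channels, montage)] <- 1
    w[intersect(c("C1", "C2", "P1", "P2", "CP3", "CP4"), montage)] <- 0.3
  } else {
    stop("unknown component: ", component)
  }
  w
}

#' Generate a single-trial ERP component kernel
#'
#' A Gaussian-in-time bump, `amplitude * exp(-(t - latency)^2 / (2 width^2))`,
#' scaled per channel by the component's spatial weights. On a maximally
#' weighted channel the kernel equals `amplitude` at `latency`; half-maximum
#' crossings sit at `latency +/- width * sqrt(2 log 2)`.
#'
#' @param component `"LOP"` or `"CPP"`.
#' @param params List with `latency_ms`, `amplitude_uv`, `width_ms` (Gaussian
#'   SD in ms); scalars.
#' @param montage Channel labels.
#' @param t_ms Time axis in ms (relative to stimulus onset).
#' @return Channels x time numeric matrix (microvolts), dimnames set.
#' @examples
#' k <- generate_erp_kernel("LOP", list(latency_ms = 350, amplitude_uv = 5,
#'                                      width_ms = 50))
#' which.max(k["O1", ])  # peaks at 350 ms
#' @export
generate_erp_kernel <- function(component, params, montage = montage_1010(),
                                t_ms = 0:1000) {
  stopifnot(params$latency_ms > 0, params$width_ms > 0)
  w <- component_weights(component, montage)
  bump <- params$amplitude_uv *
    exp(-(t_ms - params$latency_ms)^2 / (2 * params$width_ms^2))
  out <- outer(w, bump)
  dimnames(out) <- list(montage, NULL)
  out
}

# Pink (1/f^exponent power) noise, normalized to sd. The default 1/f slope
# uses the standard pole-zero "pinking" cascade (an IIR approximation flat
# to within ~0.3 dB over the EEG band) run in C; other exponents fall back
# to FFT spectral shaping with a conjugate-symmetric 1/f^(e/2) amplitude
# envelope.
pink_noise <- function(n, sd = 1, exponent = 1) {
  if (sd <= 0) return(numeric(n))
  if (exponent == 1) {
    b <- c(0.049922035, -0.095993537, 0.050612699, -0.004408786)
    a <- c(1, -2.494956002, 2.017265875, -0.522189400)
    y <- as.numeric(signal::filter(b, a, stats::rnorm(n + 1500)))[-seq_len(1500)]
  } else {
    nfft <- stats::nextn(n, 2)
    f <- stats::fft(stats::rnorm(nfft))
    k <- 0:(nfft - 1)
    phys <- pmin(k, nfft - k)
    shape <- c(0, phys[-1]^(-exponent / 2))
    y <- Re(stats::fft(f * shape, inverse = TRUE))[seq_len(n)]
  }
  sd * (y - mean(y)) / stats::sd(y)
}

pink_noise_matrix <- function(n_ch, n, sd = 1, exponent = 1) {
  t(vapply(seq_len(n_ch), function(i) pink_noise(n, sd, exponent),
           numeric(n)))
}

# Frontal-weighted blink template: half-sine of a 4 Hz cycle (~125 ms).
blink_template <- function(rate, amplitude_uv, montage) {
  n <- round(rate / 8)  # half period of 4 Hz
  shape <- amplitude_uv * sin(pi * seq(0, 1, length.out = n))
  w <- stats::setNames(numeric(length(montage)), montage)
  w[intersect(c("Fp1", "Fpz", "Fp2"), montage)] <- 1
  w[intersect(c("AF7", "AF3", "AFz", "AF4", "AF8"), montage)] <- 0.6
  w[intersect(c("F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8"), montage)] <- 0.3
  outer(w, shape)
}

# Behavioral draws for one participant; seeded independently of the EEG
# noise so behavior-only runs reproduce exactly what a full session embeds.
.draw_behavior <- function(config, participant_index) {
  set.seed(sub_seed(config$seed, "behavior", participant_index))
  bp <- config$behavior_params
  bins <- condition_bins()
  trials <- bins[rep(seq_len(nrow(bins)), each = config$n_trials_per_bin), ]
  trials <- trials[sample(nrow(trials)), ]
  rownames(trials) <- NULL

  z_rt <- stats::rnorm(1)
  sim_p <- pmin(pmax(stats::rnorm(2, bp$similarity_acc, bp$similarity_between_sd),
                     0.5), 1)
  names(sim_p) <- names(bp$similarity_acc)

  cond <- paste(trials$task, trials$scene, sep = "_")
  mu <- bp$rt_mean_s[cond]
  cv <- bp$rt_between_cv[cond]
  mu_p <- mu * exp(cv * z_rt - cv^2 / 2)
  sg <- bp$rt_trial_sigma
  trials$rt_s <- as.numeric(mu_p * exp(stats::rnorm(nrow(trials), 0, sg) - sg^2 / 2))
  trials$correct <- stats::rbinom(nrow(trials), 1, bp$detection_acc[cond]) == 1

  trials$question <- FALSE
  for (b in bins$bin[bins$task == "dual"]) {
    idx <- which(trials$bin == b)
    nq <- round(length(idx) / 3)
    if (nq > 0) trials$question[sample(idx, nq)] <- TRUE
  }
  trials$question_correct <- NA
  qi <- which(trials$question)
  trials$question_correct[qi] <-
    stats::rbinom(length(qi), 1, sim_p[trials$scene[qi]]) == 1
  trials
}

#' Generate one participant's synthetic session
#'
#' Simulates continuous multi-channel EEG plus an ordered event table. The
#' EEG is a sum of per-trial LOP and CPP kernels placed at event onsets
#' (per-bin latencies/amplitudes plus per-participant normal random effects
#' drawn once), pink and white background noise per channel, and occasional
#' frontal blink artifacts (probability `artifact_rate` per epoch). Event
#' onsets advance by the trial's reaction time plus a uniform
#' inter-stimulus interval, aligned to a 4 ms grid. Reaction times,
#' detection correctness and scene-similarity answers are drawn per
#' condition from the behavioral parameters.
#'
#' @param config A [synth_config()].
#' @param participant_index 1-based participant number
#'   (`<= config$n_participants`).
#' @return A `synthetic_session`: list with `eeg` (`eeg_continuous`),
#'   `events` (data.frame: `onset_sample`, `bin`, `correct`, `rt_s`,
#'   `question`, `question_correct`), `participant`, `effects`
#'   (the participant's random effects), `artifact_trials` (ground-truth
#'   blink positions) and `ground_truth` (the config).
#' @export
generate_session <- function(config, participant_index = 1L) {
  validate_synth_config(config)
  if (participant_index > config$n_participants)
    stop("participant_index exceeds n_participants")
  trials <- .draw_behavior(config, participant_index)

  set.seed(sub_seed(config$seed, "session", participant_index))
  rate <- config$sampling_rate
  n_ch <- length(config$montage)

  effects <- list(
    lop_latency_ms = stats::rnorm(1, 0, config$lop_params$participant_latency_sd_ms),
    lop_amplitude_uv = stats::rnorm(1, 0, config$lop_params$participant_amplitude_sd_uv),
    cpp_latency_ms = stats::rnorm(1, 0, config$cpp_params$participant_latency_sd_ms),
    cpp_amplitude_uv = stats::rnorm(1, 0, config$cpp_params$participant_amplitude_sd_uv))

  isi <- stats::runif(nrow(trials), config$isi_range[1], config$isi_range[2])
  gaps <- trials$rt_s + isi
  onsets_s <- 2 + c(0, cumsum(gaps[-length(gaps)]))
  onset <- 1L + 4L * as.integer(round(onsets_s * rate / 4))
  trials$onset_sample <- onset
  n_samp <- max(onset) + as.integer(2.2 * rate)

  if (config$couple_rt_to_cpp) {
    lat <- config$cpp_params$latency_ms[trials$bin] + effects$cpp_latency_ms
    sg <- config$behavior_params$rt_trial_sigma
    trials$rt_s <- lat / 1000 * exp(stats::rnorm(nrow(trials), 0, sg) - sg^2 / 2)
  }

  data <- matrix(0, n_ch, n_samp, dimnames = list(config$montage, NULL))
  t_ms <- 0:1000
  kern_idx <- as.integer(round(t_ms * rate / 1000))
  for (comp in c("LOP", "CPP")) {
    par <- config[[if (comp == "LOP") "lop_params" else "cpp_params"]]
    off_l <- effects[[if (comp == "LOP") "lop_latency_ms" else "cpp_latency_ms"]]
    off_a <- effects[[if (comp == "LOP") "lop_amplitude_uv" else "cpp_amplitude_uv"]]
    w <- component_weights(comp, config$montage)
    for (b in names(par$latency_ms)) {
      idx <- which(trials$bin == b)
      if (!length(idx)) next
      bump <- max(par$amplitude_uv[[b]] + off_a, 0) *
        exp(-(t_ms - (par$latency_ms[[b]] + off_l))^2 / (2 * par$width_ms^2))
      contrib <- outer(w, bump)
      for (i in idx) {
        cols <- onset[i] + kern_idx
        data[, cols] <- data[, cols] + contrib
      }
    }
  }

  if (config$noise$pink_sd > 0)
    for (ch in seq_len(n_ch))
      data[ch, ] <- data[ch, ] + pink_noise(n_samp, config$noise$pink_sd,
                                            config$noise$pink_exponent %||% 1)
  if (config$noise$white_sd > 0)
    data <- data + matrix(stats::rnorm(length(data), 0, config$noise$white_sd),
                          n_ch, n_samp)

  artifact_trials <- integer(0)
  if (config$artifact_rate > 0) {
    hit <- which(stats::runif(nrow(trials)) < config$artifact_rate)
    if (length(hit)) {
      tmpl <- blink_template(rate, config$blink_amplitude_uv, config$montage)
      for (i in hit) {
        start <- onset[i] + as.integer(stats::runif(1, 0, 0.8) * rate)
        cols <- start + seq_len(ncol(tmpl)) - 1L
        data[, cols] <- data[, cols] + tmpl
      }
      artifact_trials <- hit
    }
  }

  events <- trials[order(trials$onset_sample),
                   c("onset_sample", "bin", "correct", "rt_s",
                     "question", "question_correct")]
  rownames(events) <- NULL
  structure(list(
    eeg = eeg_continuous(data, rate, config$montage, config$reference),
    events = events,
    participant = as.integer(participant_index),
    effects = effects,
    artifact_trials = artifact_trials,
    ground_truth = config),
    class = "synthetic_session")
}

#' Behavioral records without the EEG
#'
#' Draws exactly the behavioral trials that [generate_session()] would embed
#' for the same configuration and participant (shared seeding), without
#' synthesizing the EEG — convenient for behavior-only analyses.
#'
#' @inheritParams generate_session
#' @return Data.frame of trials with `participant`, `bin`, `task`, `scene`,
#'   `is_target`, `rt_s`, `correct`, `question`, `question_correct`.
#' @export
generate_behavior_records <- function(config, participant_index = 1L) {
  tr <- .draw_behavior(config, participant_index)
  tr$participant <- sprintf("P%02d", participant_index)
  tr[, c("participant", "bin", "task", "scene", "is_target",
         "rt_s", "correct", "question", "question_correct")]
}

#' Simulate participant-level ERP waveforms directly
#'
#' Desk-scale generator of per-participant cluster-averaged ERP waveforms for
#' a given bin: the component kernels' cluster mean with per-participant
#' latency/amplitude random effects, plus smooth residual noise emulating
#' what survives trial averaging (default SD: single-trial noise SD divided
#' by `sqrt(n_trials_per_bin * n_cluster_channels)`). Used for Monte-Carlo
#' studies of the pointwise statistics where full sessions would be
#' needlessly expensive.
#'
#' @param config A [synth_config()].
#' @param bin Bin label from [condition_bins()].
#' @param cluster A [cluster_spec()].
#' @param n Number of participants to draw.
#' @param seed Integer seed.
#' @param time_ms Epoch time axis.
#' @param noise_sd Residual noise SD in microvolts; `NULL` for the default.
#' @return `n` x `length(time_ms)` matrix.
#' @export
simulate_participant_waveforms <- function(config, bin, cluster, n,
                                           seed = 1L,
                                           time_ms = seq(-200, 996, by = 4),
                                           noise_sd = NULL) {
  set.seed(as.integer(seed))
  if (is.null(noise_sd))
    noise_sd <- sqrt(config$noise$pink_sd^2 + config$noise$white_sd^2) /
      sqrt(config$n_trials_per_bin * length(cluster$channels))
  out <- matrix(0, n, length(time_ms))
  for (i in seq_len(n)) {
    wave <- numeric(length(time_ms))
    for (comp in c("LOP", "CPP")) {
      par <- config[[if (comp == "LOP") "lop_params" else "cpp_params"]]
      lat <- par$latency_ms[[bin]] + stats::rnorm(1, 0, par$participant_latency_sd_ms)
      amp <- max(par$amplitude_uv[[bin]] +
                   stats::rnorm(1, 0, par$participant_amplitude_sd_uv), 0)
      w <- component_weights(comp, config$montage)
      wbar <- mean(w[cluster$channels])
      wave <- wave + wbar * amp * exp(-(time_ms - lat)^2 / (2 * par$width_ms^2))
    }
    if (noise_sd > 0) {
      e <- stats::rnorm(length(time_ms) + 20)
      e <- stats::filter(e, rep(1 / 8, 8), sides = 2)
      e <- e[!is.na(e)][seq_along(time_ms)]
      wave <- wave + noise_sd * e / stats::sd(e)
    }
    out[i, ] <- wave
  }
  out
}

#' @export
print.synthetic_session <- function(x, ...) {
  cat(sprintf("<synthetic_session> participant %d: %d events, %d channels x %d samples @ %g Hz\n",
              x$participant, nrow(x$events), nrow(x$eeg$data),
              ncol(x$eeg$data), x$eeg$rate))
  invisible(x)
}
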