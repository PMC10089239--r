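# Ground-truth synthetic EEG cohorts: steady-state components phase-locked
# to the stimulus envelope, 1/f background noise, optional transient
# artifacts, and von Mises between-participant phase lags.

#' Configuration for a synthetic EEG cohort
#'
#' The defaults emulate the study conditions of the neonatal frequency-tagging
#' experiment: 98 scalp channels digitised at 1000 Hz, 50 trials per rhythm,
#' 17 participants (19 recorded minus 2 excluded), steady-state components at
#' the meter frequencies (0.3 uV) and the beat frequency (0.5 uV) over pink
#' (1/f) background noise of 10 uV RMS, and participant-specific phase lags
#' drawn von Mises around each component's group lag with concentration
#' `kappa`. Component frequencies snap to the nearest envelope harmonic of
#' the chosen rhythm so that a trial holds an integer number of cycles.
#'
#' @param rhythm `"duple_triple"` or `"quadruple"`.
#' @param components `data.frame` with columns `freq_hz`, `amplitude_uv`,
#'   `phase_lag_rad` (group-mean lag of the neural response behind the
#'   stimulus envelope). `NULL` gives the rhythm's default set.
#' @param n_channels,fs_hz,n_trials,n_participants Cohort geometry.
#' @param n_repetitions Pattern repeats per trial (`NULL` = the rhythm's
#'   published trial length: 19 for duple/triple, 9 for quadruple).
#' @param noise_exponent,noise_rms_uv Background 1/f^exponent noise model.
#' @param kappa Between-participant von Mises phase concentration.
#' @param artifact_rate Expected number of transient artifacts per trial.
#' @param artifact_amp_uv Peak amplitude of injected transients.
#' @param seed Integer seed; fully determines the cohort.
#' @return Object of class `synth_config`.
#' @export
synth_config <- function(rhythm = c("duple_triple", "quadruple"),
                         components = NULL, n_channels = 98, fs_hz = 1000,
                         n_trials = 50, n_participants = 17,
                         n_repetitions = NULL,
                         noise_exponent = 1, noise_rms_uv = 10, kappa = 5,
                         artifact_rate = 0, artifact_amp_uv = 300,
                         seed = 1) {
  rhythm <- match.arg(rhythm)
  if (is.null(components)) {
    components <- if (rhythm == "duple_triple")
      data.frame(freq_hz = c(1, 1.5, 3), amplitude_uv = c(0.3, 0.3, 0.5),
                 phase_lag_rad = c(1.0, -2.2, 0.8))
    else
      data.frame(freq_hz = c(0.75, 3), amplitude_uv = c(0.3, 0.5),
                 phase_lag_rad = c(-1.5, 1.1))
  }
  stopifnot(all(c("freq_hz", "amplitude_uv", "phase_lag_rad") %in%
                  names(components)),
            all(components$amplitude_uv >= 0), kappa >= 0,
            n_channels >= 1, fs_hz > 0, n_trials >= 1, n_participants >= 1)
  if (is.null(n_repetitions))
    n_repetitions <- if (rhythm == "duple_triple") 19L else 9L
  spec <- if (rhythm == "duple_triple")
    duple_triple_rhythm(n_repetitions = n_repetitions)
  else quadruple_rhythm(n_repetitions = n_repetitions)
  structure(list(rhythm = rhythm, spec = spec, components = components,
                 n_channels = as.integer(n_channels), fs_hz = fs_hz,
                 n_trials = as.integer(n_trials),
                 n_participants = as.integer(n_participants),
                 noise_exponent = noise_exponent, noise_rms_uv = noise_rms_uv,
                 kappa = kappa, artifact_rate = artifact_rate,
                 artifact_amp_uv = artifact_amp_uv, seed = as.integer(seed)),
            class = "synth_config")
}

#' Pink (1/f^exponent) noise by spectral shaping
#'
#' Gaussian white noise shaped in the frequency domain so the power spectral
#' density falls off as `1/f^exponent`, then rescaled to the requested RMS.
#' Exponent 0 gives white noise; RMS 0 gives zeros.
#'
#' @param n_samples Length of the series.
#' @param exponent Spectral slope of the PSD (positive = low-frequency
#'   dominated).
#' @param rms Target root-mean-square amplitude.
#' @param seed Optional integer seed (uses the current RNG state when
#'   `NULL`).
#' @return Numeric vector of length `n_samples`.
#' @export
pink_noise <- function(n_samples, exponent = 1, rms = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  drop(pink_noise_matrix(n_samples, 1L, exponent, rms))
}

# column-wise pink noise, one mvfft round trip for all series
pink_noise_matrix <- function(n_samples, n_series, exponent = 1, rms = 1) {
  if (rms == 0) return(matrix(0, n_samples, n_series))
  w <- matrix(stats::rnorm(n_samples * n_series), n_samples, n_series)
  if (exponent == 0) {
    s <- sqrt(colMeans(w^2))
    return(sweep(w, 2, s / rms, "/"))
  }
  X <- stats::mvfft(w)
  k <- seq_len(n_samples) - 1
  f <- pmin(k, n_samples - k)  # two-sided frequency index
  g <- c(0, f[-1]^(-exponent / 2))
  x <- Re(stats::mvfft(X * g, inverse = TRUE)) / n_samples
  s <- sqrt(colMeans(x^2))
  sweep(x, 2, s / rms, "/")
}

# Best-Fisher von Mises sampler; kappa = 0 falls back to the uniform circle.
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (kappa == 0) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u <- stats::runif(3)
      z <- cos(pi * u[1])
      f <- (1 + r * z) / (r + z)
      c0 <- kappa * (r - f)
      if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) {
        out[i] <- wrap_angle(mu + sign(u[3] - 0.5) * acos(f))
        break
      }
    }
  }
  out
}

# Smooth random topography over a generic rectangular channel grid,
# normalised to mean 1 so the scalp average preserves component amplitude.
random_topography <- function(n_channels) {
  ncol_g <- ceiling(sqrt(n_channels))
  xy <- cbind(((seq_len(n_channels) - 1) %% ncol_g) / max(1, ncol_g - 1),
              ((seq_len(n_channels) - 1) %/% ncol_g) / max(1, ncol_g - 1))
  n_bump <- 3L
  cx <- stats::runif(n_bump); cy <- stats::runif(n_bump)
  a <- stats::runif(n_bump, 0.5, 1.5); s <- stats::runif(n_bump, 0.2, 0.5)
  w <- rep(0.5, n_channels)
  for (b in seq_len(n_bump))
    w <- w + a[b] * exp(-((xy[, 1] - cx[b])^2 + (xy[, 2] - cy[b])^2) /
                          (2 * s[b]^2))
  w / mean(w)
}

#' Generate one synthetic participant
#'
#' Builds a continuous recording of back-to-back trials. Each steady-state
#' component is a sinusoid at the envelope harmonic nearest its nominal
#' frequency, with phase equal to the stimulus envelope's phase at that
#' harmonic plus the participant's lag (drawn von Mises around the
#' component's group lag), weighted by a smooth random channel topography of
#' mean 1. Independent pink noise is added per channel, plus optional
#' transient artifacts. Fully deterministic given the config seed and
#' participant id.
#'
#' @param cfg A [synth_config()].
#' @param participant_id Integer id (1-based).
#' @return List with `recording` (an [eeg_recording()]), `onsets_s` (trial
#'   onsets), `trial_duration_s`, and `truth` (per-component participant
#'   lags, amplitudes, harmonic frequencies and topographies).
#' @export
generate_participant <- function(cfg, participant_id) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(derive_seed(cfg$seed, participant_id))
  env <- build_rhythm(cfg$spec, cfg$fs_hz)
  n_trial_samp <- length(env$samples)
  trial_dur <- env$duration_s
  n_total <- n_trial_samp * cfg$n_trials
  pattern_hz <- 1000 / (cfg$spec$ioi_ms * length(cfg$spec$onset_pattern))
  # envelope reference phase at each harmonic (trial-locked DFT phase)
  E <- stats::fft(env$samples)
  comp <- cfg$components
  k_harm <- pmax(1L, round(comp$freq_hz / pattern_hz) *
                   round(n_trial_samp * pattern_hz / cfg$fs_hz))
  f_harm <- k_harm * cfg$fs_hz / n_trial_samp
  phi_env <- Arg(E[k_harm + 1L])
  lag_i <- vapply(seq_len(nrow(comp)),
                  function(j) rvonmises(1, comp$phase_lag_rad[j], cfg$kappa),
                  numeric(1))
  topo <- lapply(seq_len(nrow(comp)), function(j) random_topography(cfg$n_channels))
  t_trial <- (seq_len(n_trial_samp) - 1) / cfg$fs_hz
  signal_trial <- matrix(0, cfg$n_channels, n_trial_samp)
  for (j in seq_len(nrow(comp))) {
    s <- comp$amplitude_uv[j] *
      cos(2 * pi * f_harm[j] * t_trial + phi_env[j] + lag_i[j])
    signal_trial <- signal_trial + outer(topo[[j]], s)
  }
  data <- matrix(0, cfg$n_channels, n_total)
  for (tr in seq_len(cfg$n_trials)) {
    idx <- (tr - 1L) * n_trial_samp + seq_len(n_trial_samp)
    noise <- t(pink_noise_matrix(n_trial_samp, cfg$n_channels,
                                 cfg$noise_exponent, cfg$noise_rms_uv))
    data[, idx] <- signal_trial + noise
  }
  if (cfg$artifact_rate > 0) {
    n_art <- stats::rpois(1, cfg$artifact_rate * cfg$n_trials)
    for (a in seq_len(n_art)) {
      ch <- sample.int(cfg$n_channels, 1)
      pos <- sample.int(n_total - round(cfg$fs_hz / 2), 1)
      half <- round(cfg$fs_hz / 4)
      shape <- cfg$artifact_amp_uv *
        exp(-((seq_len(2 * half) - half)^2) / (2 * (half / 3)^2))
      data[ch, pos + seq_len(2 * half) - 1] <-
        data[ch, pos + seq_len(2 * half) - 1] + shape * sign(stats::runif(1) - 0.5)
    }
  }
  list(recording = eeg_recording(data, cfg$fs_hz,
                                 paste0("E", seq_len(cfg$n_channels)), "Cz"),
       onsets_s = (seq_len(cfg$n_trials) - 1L) * trial_dur,
       trial_duration_s = trial_dur,
       truth = list(participant_id = participant_id,
                    freq_hz = f_harm, nominal_freq_hz = comp$freq_hz,
                    amplitude_uv = comp$amplitude_uv,
                    group_lag_rad = comp$phase_lag_rad,
                    participant_lag_rad = lag_i,
                    topography = topo))
}

#' Generate a full synthetic cohort
#'
#' @param cfg A [synth_config()].
#' @return Object of class `synth_dataset`: list with `participants` (each a
#'   [generate_participant()] result), `cfg`, and `truth` (the per-participant
#'   ground-truth records collected for convenience).
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  participants <- lapply(seq_len(cfg$n_participants),
                         function(i) generate_participant(cfg, i))
  structure(list(participants = participants, cfg = cfg,
                 truth = lapply(participants, `[[`, "truth")),
            class = "synth_dataset")
}
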