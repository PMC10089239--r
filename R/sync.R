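# Brain-stimulus phase synchronization: Morlet time-frequency phases,
# the complex synchronization index SI, and circular statistics across
# participants (Rayleigh test, circular mean).

#' Morlet wavelet time-frequency decomposition
#'
#' Complex Morlet coefficients (Gaussian-windowed complex exponentials of
#' `n_cycles` cycles, default 7) at the requested frequencies, sampled every
#' `step_ms` milliseconds (snapped to a whole number of samples). Computed by
#' FFT convolution with zero padding beyond the wavelet half-width; wavelets
#' are unit-energy normalised, so magnitudes are comparable across
#' frequencies.
#'
#' @param x Single-channel signal.
#' @param fs_hz Sampling rate in Hz.
#' @param freqs_hz Analysis frequencies in Hz.
#' @param n_cycles Wavelet length in cycles.
#' @param step_ms Output time step in milliseconds.
#' @return Object of class `morlet_tf`: `coef` (frequencies x times, complex),
#'   `times_s`, `freqs_hz`, `fs_hz`, `step_s`.
#' @export
morlet_tf <- function(x, fs_hz, freqs_hz, n_cycles = 7, step_ms = 2) {
  n <- length(x)
  if (n < n_cycles / min(freqs_hz) * fs_hz)
    stop("signal shorter than ", n_cycles, " cycles of the lowest frequency")
  step <- max(1L, round(step_ms / 1000 * fs_hz))
  half_max <- ceiling(3.5 * n_cycles / (2 * pi * min(freqs_hz)) * fs_hz)
  nfft <- next_fft_len(n + 2L * half_max)
  X <- stats::fft(c(x, rep(0, nfft - n)))
  t_idx <- seq(1L, n, by = step)
  coef <- matrix(0i, length(freqs_hz), length(t_idx))
  for (j in seq_along(freqs_hz)) {
    f <- freqs_hz[j]
    sigma_t <- n_cycles / (2 * pi * f)
    half <- ceiling(3.5 * sigma_t * fs_hz)
    tt <- (-half:half) / fs_hz
    w <- exp(-tt^2 / (2 * sigma_t^2)) * exp(2i * pi * f * tt)
    w <- w / sqrt(sum(Mod(w)^2))
    # centre the wavelet: circular shift so coefficient k aligns with sample k
    wp <- complex(length.out = nfft)
    wp[c((nfft - half + 1):nfft, 1:(half + 1))] <- w
    y <- stats::fft(X * stats::fft(wp), inverse = TRUE) / nfft
    coef[j, ] <- y[t_idx]
  }
  structure(list(coef = coef, times_s = (t_idx - 1L) / fs_hz,
                 freqs_hz = freqs_hz, fs_hz = fs_hz, step_s = step / fs_hz),
            class = "morlet_tf")
}

#' Trim the edges of a time-frequency decomposition
#'
#' Removes `trim_s` seconds from each end of the time axis, discarding
#' wavelet edge effects and onset/offset transients (2 s per side for the
#' six-beat rhythm trials, 4 s per side for the twelve-beat rhythm).
#'
#' @param tf A `morlet_tf`.
#' @param trim_s Seconds to remove from each end.
#' @return The trimmed `morlet_tf`.
#' @export
trim_edges <- function(tf, trim_s) {
  stopifnot(inherits(tf, "morlet_tf"))
  if (trim_s == 0) return(tf)
  dur <- max(tf$times_s) - min(tf$times_s)
  if (trim_s < 0 || 2 * trim_s >= dur)
    stop("trim_s must be non-negative and less than half the duration")
  keep <- tf$times_s >= (min(tf$times_s) + trim_s) &
    tf$times_s <= (max(tf$times_s) - trim_s)
  tf$coef <- tf$coef[, keep, drop = FALSE]
  tf$times_s <- tf$times_s[keep]
  tf
}

#' Phase time series from magnitude-normalised trial-averaged coefficients
#'
#' Each trial's complex coefficients are normalised to unit magnitude
#' (discarding amplitude information), averaged across trials, and the phase
#' of the average is taken (`method = "coef_average"`, the default). The
#' alternative `"phase_average"` extracts the phase per trial and averages
#' the unit phasors of the phases, which weights trials equally even when
#' the averaged coefficient is small.
#'
#' @param tf_list List of `morlet_tf` objects, one per trial, on identical
#'   axes.
#' @param method `"coef_average"` or `"phase_average"` (identical for
#'   unit-normalised inputs; kept distinct for clarity of provenance).
#' @return Object of class `phase_series`: `theta` (frequencies x times, in
#'   (-pi, pi]), `times_s`, `freqs_hz`.
#' @export
phase_series <- function(tf_list, method = c("coef_average", "phase_average")) {
  method <- match.arg(method)
  stopifnot(length(tf_list) >= 1)
  acc <- 0
  for (tf in tf_list) {
    stopifnot(inherits(tf, "morlet_tf"))
    u <- tf$coef / Mod(tf$coef)
    u[!is.finite(u)] <- 0i
    if (method == "phase_average") u <- exp(1i * Arg(u))
    acc <- acc + u
  }
  tf1 <- tf_list[[1]]
  structure(list(theta = Arg(acc), times_s = tf1$times_s,
                 freqs_hz = tf1$freqs_hz, n_trials = length(tf_list)),
            class = "phase_series")
}

#' Brain-stimulus synchronization index
#'
#' The complex SI at each frequency is the time average of the unit phasor
#' of the EEG-minus-stimulus phase difference:
#' `SI(f) = (1/N) sum_t exp(i (theta_EEG(t,f) - theta_stim(t,f)))`.
#' Its magnitude (in [0, 1]) measures the strength of phase locking and its
#' angle the phase lag of the neural response behind the stimulus envelope.
#'
#' @param theta_eeg,theta_stim `phase_series` objects on identical time and
#'   frequency axes.
#' @return Object of class `sync_index`: complex vector `si` per frequency,
#'   `freqs_hz`, `n_timepoints`.
#' @export
sync_index <- function(theta_eeg, theta_stim) {
  stopifnot(inherits(theta_eeg, "phase_series"), inherits(theta_stim, "phase_series"))
  if (!isTRUE(all.equal(theta_eeg$freqs_hz, theta_stim$freqs_hz)) ||
      !isTRUE(all.equal(theta_eeg$times_s, theta_stim$times_s)))
    stop("phase series axes do not match")
  dphi <- theta_eeg$theta - theta_stim$theta
  si <- rowMeans(exp(1i * dphi))
  structure(list(si = si, freqs_hz = theta_eeg$freqs_hz,
                 n_timepoints = ncol(dphi)),
            class = "sync_index")
}

#' Rayleigh test of circular non-uniformity
#'
#' Tests whether a sample of angles is concentrated rather than uniform on
#' the circle. `R` is the mean resultant length, the statistic is
#' `z = n R^2`, and the p value uses the standard small-sample approximation
#' `p = exp(sqrt(1 + 4n + 4(n^2 - (nR)^2)) - (1 + 2n))`.
#'
#' @param angles Angles in radians.
#' @return List with `n`, `r` (mean resultant length), `z`, `p`,
#'   `mean_angle`.
#' @export
rayleigh_test <- function(angles) {
  n <- length(angles)
  if (n < 3L) stop("Rayleigh test needs at least 3 angles")
  m <- mean(exp(1i * angles))
  r <- Mod(m)
  R <- n * r
  z <- R^2 / n
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - R^2)) - (1 + 2 * n))
  list(n = n, r = r, z = z, p = min(1, p), mean_angle = Arg(m))
}

#' Circular mean of angles
#' @param angles Angles in radians.
#' @return Mean direction in (-pi, pi].
#' @export
circular_mean <- function(angles) Arg(mean(exp(1i * angles)))

#' Group topography of synchronization strength and phase-lag consistency
#'
#' Per electrode: mean |SI| across participants, a Rayleigh test on the SI
#' angles across participants (consistent phase lag implies non-uniform
#' angles), a significance mask at `alpha`, and the circular group-mean
#' angle.
#'
#' @param si_mat Participants x electrodes complex matrix of SI values at one
#'   frequency.
#' @param alpha Significance level for the mask (default 0.05).
#' @param electrode_labels Optional electrode names.
#' @return `data.frame` with `electrode`, `mean_strength`, `rayleigh_p`,
#'   `significant`, `mean_angle_rad`, `mean_angle_deg`.
#' @export
sync_topography <- function(si_mat, alpha = 0.05, electrode_labels = NULL) {
  si_mat <- as.matrix(si_mat)
  if (nrow(si_mat) < 3L) stop("need at least 3 participants")
  n_el <- ncol(si_mat)
  if (is.null(electrode_labels)) electrode_labels <- paste0("E", seq_len(n_el))
  ray <- lapply(seq_len(n_el), function(e) rayleigh_test(Arg(si_mat[, e])))
  p <- vapply(ray, `[[`, numeric(1), "p")
  ang <- vapply(ray, `[[`, numeric(1), "mean_angle")
  data.frame(electrode = electrode_labels,
             mean_strength = colMeans(Mod(si_mat)),
             rayleigh_p = p, significant = p < alpha,
             mean_angle_rad = ang, mean_angle_deg = ang * 180 / pi)
}

#' Full brain-stimulus synchronization analysis of a trial set
#'
#' Runs the Morlet pathway on every kept trial of every electrode and on the
#' rendered stimulus envelope (through the identical wavelet settings, so
#' filter delays cancel in the phase difference), trims the trial edges,
#' forms magnitude-normalised trial-averaged phase series, and returns the
#' complex SI per electrode and frequency.
#'
#' @param tset A `trial_set`.
#' @param envelope A `stimulus_envelope` covering one trial at the trial
#'   sampling rate.
#' @param freqs_hz Frequencies at which to evaluate SI.
#' @param trim_s Seconds trimmed from each end of every trial.
#' @param n_cycles,step_ms Morlet parameters.
#' @param method Phase-averaging method, see [phase_series()].
#' @return Electrodes x frequencies complex matrix of SI values, with
#'   electrode labels as row names and frequencies as column names.
#' @export
sync_analysis <- function(tset, envelope, freqs_hz, trim_s = 2,
                          n_cycles = 7, step_ms = 2,
                          method = "coef_average") {
  stopifnot(inherits(tset, "trial_set"), inherits(envelope, "stimulus_envelope"))
  if (abs(envelope$fs_hz - tset$fs_hz) > 1e-9)
    stop("envelope and trials must share a sampling rate")
  n_trial <- dim(tset$trials)[1]; n_ch <- dim(tset$trials)[2]
  n_samp <- dim(tset$trials)[3]
  env <- envelope$samples[seq_len(min(n_samp, length(envelope$samples)))]
  if (length(env) < n_samp) env <- c(env, rep(0, n_samp - length(env)))
  stim_tf <- trim_edges(morlet_tf(env, tset$fs_hz, freqs_hz, n_cycles, step_ms),
                        trim_s)
  theta_stim <- phase_series(list(stim_tf), method)
  si <- matrix(0i, n_ch, length(freqs_hz),
               dimnames = list(tset$channel_labels, freqs_hz))
  keep_t <- theta_stim$times_s
  for (ch in seq_len(n_ch)) {
    kept <- which(tset$kept_mask[, ch])
    if (!length(kept)) { si[ch, ] <- NA; next }
    X <- t(matrix(tset$trials[kept, ch, , drop = FALSE], nrow = length(kept)))
    coefs <- morlet_batch(X, tset$fs_hz, freqs_hz, n_cycles, step_ms, keep_t)
    for (j in seq_along(freqs_hz)) {
      u <- coefs[[j]] / Mod(coefs[[j]])
      u[!is.finite(u)] <- 0i
      theta <- Arg(rowMeans(u))
      si[ch, j] <- mean(exp(1i * (theta - theta_stim$theta[j, ])))
    }
  }
  si
}

# Batched Morlet coefficients for several trials of one channel: one forward
# mvfft shared across frequencies. Returns, per frequency, a complex
# times x trials matrix restricted to the requested output times.
morlet_batch <- function(X, fs_hz, freqs_hz, n_cycles, step_ms, times_s) {
  n <- nrow(X)
  step <- max(1L, round(step_ms / 1000 * fs_hz))
  half_max <- ceiling(3.5 * n_cycles / (2 * pi * min(freqs_hz)) * fs_hz)
  nfft <- next_fft_len(n + 2L * half_max)
  Xp <- rbind(X, matrix(0, nfft - n, ncol(X)))
  XF <- stats::mvfft(Xp)
  t_idx <- seq(1L, n, by = step)
  sel <- which(round((t_idx - 1L) / fs_hz, 9) %in% round(times_s, 9))
  lapply(freqs_hz, function(f) {
    sigma_t <- n_cycles / (2 * pi * f)
    half <- ceiling(3.5 * sigma_t * fs_hz)
    tt <- (-half:half) / fs_hz
    w <- exp(-tt^2 / (2 * sigma_t^2)) * exp(2i * pi * f * tt)
    w <- w / sqrt(sum(Mod(w)^2))
    wp <- complex(length.out = nfft)
    wp[c((nfft - half + 1):nfft, 1:(half + 1))] <- w
    Y <- stats::mvfft(XF * stats::fft(wp), inverse = TRUE) / nfft
    Y[t_idx[sel], , drop = FALSE]
  })
}
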