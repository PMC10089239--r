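# Frequency-tagging spectral analysis: trial averaging, DFT amplitude
# spectra, neighbour-bin noise subtraction, target-frequency extraction and
# group-level enhancement statistics.

#' Average trials channel-wise, honouring the rejection mask
#'
#' Arithmetic mean across kept trials for each channel; a channel marked bad
#' in a trial does not contribute to that channel's average. Channels kept in
#' no trial come back as `NA` rows (excluded downstream by [scalp_average()]).
#'
#' @param tset A `trial_set`.
#' @return Channels x samples matrix of trial-averaged EEG.
#' @export
average_trials <- function(tset) {
  stopifnot(inherits(tset, "trial_set"))
  n_trial <- dim(tset$trials)[1]
  if (n_trial < 1L) stop("no trials to average")
  n_ch <- dim(tset$trials)[2]; n_samp <- dim(tset$trials)[3]
  out <- matrix(NA_real_, n_ch, n_samp)
  for (ch in seq_len(n_ch)) {
    keep <- tset$kept_mask[, ch]
    if (!any(keep)) next
    sub <- tset$trials[keep, ch, , drop = FALSE]
    out[ch, ] <- colMeans(matrix(sub, nrow = sum(keep)))
  }
  rownames(out) <- tset$channel_labels
  out
}

#' Amplitude spectrum of averaged EEG
#'
#' One-sided DFT amplitude spectrum per channel with the convention
#' `2|X_k|/N` for k > 0 (and `|X_0|/N` at DC), so a unit-amplitude sinusoid
#' spanning an integer number of cycles reads 1.0 at its bin. The frequency
#' resolution is `fs/N = 1/duration`; a 36 s trial gives 0.0278 Hz
#' (printed as 0.028 Hz).
#'
#' @param x Channels x samples matrix (or a vector for one channel).
#' @param fs_hz Sampling rate in Hz.
#' @return Object of class `amplitude_spectrum`: `freqs_hz` (bin centres from
#'   0), `amps` (channels x bins, microvolts), `resolution_hz`, `fs_hz`.
#' @export
amplitude_spectrum <- function(x, fs_hz) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (anyNA(x)) {
    bad <- rowSums(is.na(x)) > 0
    x[bad, ] <- 0  # NA channels re-flagged below
  } else bad <- rep(FALSE, nrow(x))
  n <- ncol(x)
  X <- stats::mvfft(t(x))
  n_bins <- floor(n / 2) + 1L
  amps <- t(Mod(X[seq_len(n_bins), , drop = FALSE])) * 2 / n
  amps[, 1] <- amps[, 1] / 2
  amps[bad, ] <- NA_real_
  structure(list(freqs_hz = (seq_len(n_bins) - 1) * fs_hz / n,
                 amps = amps, resolution_hz = fs_hz / n, fs_hz = fs_hz,
                 channel_labels = rownames(x)),
            class = "amplitude_spectrum")
}

#' Neighbour-bin noise subtraction
#'
#' Removes the contribution of residual background noise at every bin by
#' subtracting the mean amplitude of the surrounding bins, under the
#' assumption that without a steady-state response the amplitude at a bin
#' equals the local average. The default window spans bins -5..-3 and +3..+5
#' around each bin (at 0.028 Hz resolution, -0.15 to -0.07 Hz and +0.07 to
#' +0.15 Hz), leaving a one-bin guard around the evaluated bin. Corrected
#' values may legitimately be negative; they are not floored, since flooring
#' would bias comparisons against the noise floor. Bins without the full
#' neighbour set are flagged in `edge_flag` and should be excluded from
#' statistics.
#'
#' @param spec An [amplitude_spectrum()].
#' @param window_bins Integer pair `c(inner, outer)` giving the neighbour
#'   window on each side; default `c(3, 5)`.
#' @return Object of class `noise_corrected_spectrum` (inherits
#'   `amplitude_spectrum`) with `amps` replaced by corrected values and an
#'   `edge_flag` logical vector per bin.
#' @export
noise_subtract <- function(spec, window_bins = c(3, 5)) {
  stopifnot(inherits(spec, "amplitude_spectrum"))
  inner <- window_bins[1]; outer <- window_bins[2]
  stopifnot(inner >= 1, outer >= inner)
  offs <- c(-(outer:inner), inner:outer)
  n_bins <- length(spec$freqs_hz)
  corrected <- spec$amps
  edge <- logical(n_bins)
  for (k in seq_len(n_bins)) {
    idx <- k + offs
    if (any(idx < 1L | idx > n_bins)) {
      edge[k] <- TRUE
      corrected[, k] <- NA_real_
    } else {
      corrected[, k] <- spec$amps[, k] -
        rowMeans(spec$amps[, idx, drop = FALSE])
    }
  }
  out <- spec
  out$amps <- corrected
  out$window_bins <- c(inner, outer)
  out$edge_flag <- edge
  class(out) <- c("noise_corrected_spectrum", "amplitude_spectrum")
  out
}

#' Average a spectrum across scalp electrodes
#'
#' Collapses a multi-electrode spectrum to the all-scalp mean, the form used
#' for group statistics so that no electrode subset is hand-picked.
#'
#' @param spec An `amplitude_spectrum` (or noise-corrected spectrum).
#' @return The same class of object with a single averaged electrode row.
#' @export
scalp_average <- function(spec) {
  stopifnot(inherits(spec, "amplitude_spectrum"))
  spec$amps <- matrix(colMeans(spec$amps, na.rm = TRUE), nrow = 1,
                      dimnames = list("scalp_mean", NULL))
  spec$channel_labels <- "scalp_mean"
  spec
}

#' Stimulus-related and unrelated frequency sets
#'
#' Frequencies with energy in each rhythm's envelope spectrum (used to read
#' out the steady-state responses) and interleaved frequencies with none
#' (whose mean corrected amplitude defines the noise floor). Frequencies at
#' or below the 0.5 Hz high-pass cutoff are excluded.
#'
#' @param rhythm `"duple_triple"` or `"quadruple"`.
#' @return List with `related_hz` and `unrelated_hz`.
#' @export
target_frequency_sets <- function(rhythm = c("duple_triple", "quadruple")) {
  rhythm <- match.arg(rhythm)
  if (rhythm == "duple_triple")
    list(related_hz = c(1, 1.5, 2, 2.5, 3),
         unrelated_hz = c(0.75, 1.25, 1.75, 2.25, 2.75))
  else
    list(related_hz = seq(0.75, 3, by = 0.25),
         unrelated_hz = seq(0.625, 2.875, by = 0.25))
}

#' Read target-frequency amplitudes and the noise floor off a spectrum
#'
#' Nearest-bin lookup of each listed frequency (with a warning when the
#' nearest bin is more than half a bin away, which can happen when the
#' inter-onset interval and the nominal tempo disagree by rounding). The
#' noise floor is the mean amplitude over the unrelated set.
#'
#' @param spec A single-electrode (e.g. scalp-averaged) spectrum.
#' @param sets A [target_frequency_sets()] list.
#' @return List with named vectors `related`, `unrelated`, the scalar
#'   `noise_floor`, and `bin_freqs` giving the actual bin centres used.
#' @export
extract_target_amplitudes <- function(spec, sets) {
  stopifnot(inherits(spec, "amplitude_spectrum"))
  if (nrow(spec$amps) != 1L)
    stop("extract_target_amplitudes expects a single (scalp-averaged) spectrum")
  lookup <- function(f) {
    k <- which.min(abs(spec$freqs_hz - f))
    if (abs(spec$freqs_hz[k] - f) > 0.5 * spec$resolution_hz)
      warning(sprintf("frequency %g Hz is %.4g Hz from the nearest bin",
                      f, abs(spec$freqs_hz[k] - f)))
    k
  }
  k_rel <- vapply(sets$related_hz, lookup, 1L)
  k_unr <- vapply(sets$unrelated_hz, lookup, 1L)
  related <- stats::setNames(spec$amps[1, k_rel], sets$related_hz)
  unrelated <- stats::setNames(spec$amps[1, k_unr], sets$unrelated_hz)
  list(related = related, unrelated = unrelated,
       noise_floor = mean(unrelated),
       bin_freqs = list(related = spec$freqs_hz[k_rel],
                        unrelated = spec$freqs_hz[k_unr]))
}

#' Group-level test of target amplitudes against the noise floor
#'
#' Paired-samples t test, per stimulus-related frequency, of each
#' participant's amplitude against that participant's average noise floor,
#' Bonferroni-corrected over the related set. Effect size is Cohen's d for
#' paired data, `mean(diff) / sd(diff)`. A degenerate zero-variance
#' difference is flagged (`degenerate = TRUE`, `p` reported as 0 when the
#' mean difference is non-zero, 1 otherwise).
#'
#' @param related_amps Participants x frequencies matrix (column names are
#'   frequencies in Hz).
#' @param noise_floor Numeric vector, one noise-floor value per participant.
#' @return `data.frame` with columns `freq_hz`, `mean_diff`, `t`, `df`,
#'   `p_raw`, `p_bonferroni`, `cohens_d`, `degenerate`.
#' @export
group_test <- function(related_amps, noise_floor) {
  related_amps <- as.matrix(related_amps)
  n <- nrow(related_amps)
  if (n < 2L) stop("need at least 2 participants")
  stopifnot(length(noise_floor) == n)
  m <- ncol(related_amps)
  res <- lapply(seq_len(m), function(j) {
    d <- related_amps[, j] - noise_floor
    if (stats::sd(d) == 0) {
      data.frame(mean_diff = mean(d), t = ifelse(mean(d) == 0, 0, Inf),
                 df = n - 1, p_raw = ifelse(mean(d) == 0, 1, 0),
                 cohens_d = ifelse(mean(d) == 0, 0, Inf), degenerate = TRUE)
    } else {
      tt <- stats::t.test(d)
      data.frame(mean_diff = mean(d), t = unname(tt$statistic),
                 df = unname(tt$parameter), p_raw = tt$p.value,
                 cohens_d = mean(d) / stats::sd(d), degenerate = FALSE)
    }
  })
  res <- do.call(rbind, res)
  freq_names <- colnames(related_amps)
  res <- cbind(freq_hz = if (is.null(freq_names)) seq_len(m)
               else as.numeric(freq_names), res)
  res$p_bonferroni <- pmin(1, res$p_raw * m)
  rownames(res) <- NULL
  res[, c("freq_hz", "mean_diff", "t", "df", "p_raw", "p_bonferroni",
          "cohens_d", "degenerate")]
}

#' Normalise amplitudes by the beat-frequency amplitude
#'
#' Expresses each meter-related amplitude relative to the 3 Hz beat
#' amplitude, so stimulus and EEG spectra can be compared on a common scale
#' (the beat maps to 1).
#'
#' @param amps Named numeric vector of amplitudes (names = frequency in Hz).
#' @param beat_hz Beat frequency, default 3.
#' @return Named vector of normalised amplitudes.
#' @export
normalize_by_beat <- function(amps, beat_hz = 3) {
  nm <- as.numeric(names(amps))
  k <- which.min(abs(nm - beat_hz))
  if (abs(nm[k] - beat_hz) > 1e-6)
    stop("beat frequency not present in the amplitude vector")
  if (!is.finite(amps[k]) || amps[k] <= 0) stop("beat amplitude must be > 0")
  amps / amps[k]
}

#' Compare beat-normalised EEG amplitudes against the stimulus envelope
#'
#' One-sample (paired against a constant) t test per meter frequency of the
#' participants' beat-normalised EEG amplitudes against the beat-normalised
#' stimulus-envelope amplitude; a significantly larger EEG value indicates
#' selective neural enhancement of that metrical level beyond the acoustic
#' input. A zero-variance difference with non-zero mean is flagged
#' (`degenerate = TRUE`, infinite d).
#'
#' @param eeg_norm Participants x frequencies matrix of beat-normalised EEG
#'   amplitudes (column names = frequency in Hz).
#' @param stim_norm Named vector of beat-normalised stimulus amplitudes at
#'   the same frequencies.
#' @return `data.frame` with `freq_hz`, `stim_value`, `mean_eeg`, `t`, `df`,
#'   `p`, `cohens_d`, `degenerate`.
#' @export
compare_eeg_vs_stimulus <- function(eeg_norm, stim_norm) {
  eeg_norm <- as.matrix(eeg_norm)
  stopifnot(ncol(eeg_norm) == length(stim_norm))
  n <- nrow(eeg_norm)
  res <- lapply(seq_len(ncol(eeg_norm)), function(j) {
    d <- eeg_norm[, j] - stim_norm[j]
    if (stats::sd(d) == 0) {
      data.frame(stim_value = unname(stim_norm[j]), mean_eeg = mean(eeg_norm[, j]),
                 t = ifelse(mean(d) == 0, 0, Inf), df = n - 1,
                 p = ifelse(mean(d) == 0, 1, 0),
                 cohens_d = ifelse(mean(d) == 0, 0, Inf), degenerate = TRUE)
    } else {
      tt <- stats::t.test(d)
      data.frame(stim_value = unname(stim_norm[j]), mean_eeg = mean(eeg_norm[, j]),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, cohens_d = mean(d) / stats::sd(d),
                 degenerate = FALSE)
    }
  })
  res <- do.call(rbind, res)
  nm <- names(stim_norm)
  res <- cbind(freq_hz = if (is.null(nm)) seq_along(stim_norm)
               else as.numeric(nm), res)
  rownames(res) <- NULL
  res
}
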