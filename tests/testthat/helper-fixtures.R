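# Fixture builders shared across tests. All fixtures are generated in code.

# A trial set built directly from a trial x channel x sample array.
make_trial_set <- function(trials, fs_hz, rhythm = "test",
                           labels = paste0("E", seq_len(dim(trials)[2]))) {
  structure(list(trials = trials, fs_hz = fs_hz, rhythm = rhythm,
                 channel_labels = labels,
                 kept_mask = matrix(TRUE, dim(trials)[1], dim(trials)[2])),
            class = "trial_set")
}

# Single-row amplitude spectrum from a plain numeric vector (unit bin width).
make_spectrum <- function(amps, resolution_hz = 1) {
  structure(list(freqs_hz = (seq_along(amps) - 1) * resolution_hz,
                 amps = matrix(amps, nrow = 1),
                 resolution_hz = resolution_hz,
                 fs_hz = 2 * resolution_hz * (length(amps) - 1),
                 channel_labels = "E1"),
            class = "amplitude_spectrum")
}

# Multi-channel sinusoidal recording: sum_j amp[j] * cos(2 pi f[j] t + ph[j])
# weighted per channel, long enough for the 6-s band-pass taps.
make_sine_recording <- function(freqs, amps, weights, fs_hz = 250,
                                dur_s = 40, phases = rep(0, length(freqs))) {
  t <- seq(0, dur_s - 1 / fs_hz, by = 1 / fs_hz)
  s <- rep(0, length(t))
  base <- mapply(function(f, a, p) a * cos(2 * pi * f * t + p),
                 freqs, amps, phases, SIMPLIFY = FALSE)
  data <- do.call(rbind, lapply(weights, function(w)
    Reduce(`+`, base) * w))
  eeg_recording(data, fs_hz)
}

# Amplitude at the bin nearest f.
amp_at <- function(x, fs_hz, f) {
  sp <- amplitude_spectrum(x, fs_hz)
  sp$amps[1, which.min(abs(sp$freqs_hz - f))]
}
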