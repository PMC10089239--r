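# Rhythmic stimulus construction: onset patterns, temporal envelopes,
# envelope spectra, nominal beat/meter frequencies and the session schedule.

#' Describe a rhythmic stimulus pattern
#'
#' A rhythm is a fixed cycle of equally spaced beat slots, each either sounded
#' (a percussive tone) or silent (a rest), repeated a number of times per
#' trial. With a 333 ms inter-onset interval the beat rate is nominally 3 Hz
#' (180 beats per minute), and grouping beats by 2, 3 or 4 yields the duple
#' (1.5 Hz), triple (1 Hz) and quadruple (0.75 Hz) meter rates.
#'
#' @param name Label for the rhythm.
#' @param onset_pattern Logical vector, one element per beat slot: `TRUE` for a
#'   sounded tone, `FALSE` for a rest. Must contain at least one of each.
#' @param ioi_ms Inter-onset interval between consecutive beat slots, in
#'   milliseconds. Default 333 ms (printed pattern durations of 1.998 s for a
#'   6-slot and 3.996 s for a 12-slot cycle follow from this value).
#' @param n_repetitions Number of times the cycle repeats within one trial.
#' @param attack_ms,decay_ms Percussive tone shape: linear attack time and
#'   exponential decay time constant, in milliseconds.
#' @return An object of class `rhythm_spec`.
#' @export
rhythm_spec <- function(name, onset_pattern, ioi_ms = 333, n_repetitions = 1,
                        attack_ms = 5, decay_ms = 100) {
  if (length(onset_pattern) == 0L) stop("invalid rhythm spec: empty onset pattern")
  if (!is.logical(onset_pattern) || anyNA(onset_pattern))
    stop("invalid rhythm spec: onset_pattern must be logical without NA")
  if (!any(onset_pattern))
    stop("invalid rhythm spec: pattern must contain at least one tone")
  if (!is.numeric(ioi_ms) || ioi_ms <= 0) stop("invalid rhythm spec: ioi_ms must be > 0")
  if (n_repetitions < 1) stop("invalid rhythm spec: n_repetitions must be >= 1")
  structure(
    list(name = name, onset_pattern = onset_pattern, ioi_ms = ioi_ms,
         n_repetitions = as.integer(n_repetitions),
         attack_ms = attack_ms, decay_ms = decay_ms),
    class = "rhythm_spec")
}

#' Built-in rhythms
#'
#' `duple_triple_rhythm()` is a six-slot cycle (1.998 s at the default 333 ms
#' inter-onset interval) repeated 19 times for 38 s trials; it is metrically
#' ambiguous between grouping by two (1.5 Hz) and by three (1 Hz).
#' `quadruple_rhythm()` is a twelve-slot cycle (3.996 s) repeated 9 times for
#' 36 s trials, with a four-beat (0.75 Hz) grouping. The exact sounded/silent
#' slot assignments are reconstructions of the source rhythms (the published
#' patterns are shown only graphically); any pattern of the right length can
#' be substituted via `rhythm_spec()`.
#'
#' @param ioi_ms Inter-onset interval in milliseconds.
#' @param n_repetitions Cycle repeats per trial.
#' @return A `rhythm_spec`.
#' @export
duple_triple_rhythm <- function(ioi_ms = 333, n_repetitions = 19) {
  rhythm_spec("duple_triple",
              c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
              ioi_ms = ioi_ms, n_repetitions = n_repetitions)
}

#' @rdname duple_triple_rhythm
#' @export
quadruple_rhythm <- function(ioi_ms = 333, n_repetitions = 9) {
  rhythm_spec("quadruple",
              c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, FALSE, FALSE),
              ioi_ms = ioi_ms, n_repetitions = n_repetitions)
}

#' Render the temporal envelope of a rhythm
#'
#' Places one percussive amplitude burst (linear attack, exponential decay,
#' truncated at the slot boundary) in every sounded slot and silence in every
#' rest, tiled over the trial's repetitions.
#'
#' @param spec A [rhythm_spec()].
#' @param fs_hz Sampling rate in Hz; 100 Hz upwards is ample for envelope work.
#' @return An object of class `stimulus_envelope`: list with `samples`
#'   (non-negative amplitude), `fs_hz` and `duration_s`.
#' @export
build_rhythm <- function(spec, fs_hz) {
  stopifnot(inherits(spec, "rhythm_spec"))
  if (fs_hz <= 0) stop("fs_hz must be positive")
  slot_n <- spec$ioi_ms / 1000 * fs_hz
  n_slots <- length(spec$onset_pattern)
  total_n <- round(slot_n * n_slots * spec$n_repetitions)
  t_slot <- seq_len(ceiling(slot_n)) / fs_hz  # time within a slot, from 1/fs
  attack <- spec$attack_ms / 1000
  burst <- ifelse(t_slot <= attack, t_slot / attack,
                  exp(-(t_slot - attack) / (spec$decay_ms / 1000)))
  env <- numeric(total_n)
  onsets <- which(rep(spec$onset_pattern, spec$n_repetitions)) - 1L
  for (k in onsets) {
    i0 <- round(k * slot_n)
    idx <- seq_along(burst) + i0
    keep <- idx <= total_n & idx <= round((k + 1) * slot_n)
    env[idx[keep]] <- burst[keep]
  }
  structure(list(samples = env, fs_hz = fs_hz, duration_s = total_n / fs_hz),
            class = "stimulus_envelope")
}

#' Amplitude envelope of a waveform via the Hilbert transform
#'
#' Returns the modulus of the analytic signal, the standard broadband
#' amplitude envelope used to summarise the acoustic energy of a stimulus.
#'
#' @param x Real-valued waveform.
#' @param fs_hz Sampling rate in Hz.
#' @return A `stimulus_envelope`.
#' @export
hilbert_envelope <- function(x, fs_hz) {
  if (length(x) == 0L) stop("empty input signal")
  if (!all(is.finite(x))) stop("waveform must be finite")
  env <- Mod(analytic_signal(x))
  structure(list(samples = env, fs_hz = fs_hz, duration_s = length(x) / fs_hz),
            class = "stimulus_envelope")
}

#' Amplitude spectrum of a stimulus envelope
#'
#' Discrete Fourier transform of the envelope with the amplitude convention
#' `2|X_k|/N` (a unit-amplitude sinusoid occupying a whole number of cycles
#' reads 1.0 at its bin). Bin spacing is `1/duration_s`, so a trial containing
#' an integer number of pattern cycles places all envelope harmonics on exact
#' bins.
#'
#' @param env A `stimulus_envelope`.
#' @return An `amplitude_spectrum` (see [amplitude_spectrum()]) with one row.
#' @export
envelope_spectrum <- function(env) {
  stopifnot(inherits(env, "stimulus_envelope"))
  if (env$duration_s <= 0) stop("envelope has zero duration")
  amplitude_spectrum(matrix(env$samples, nrow = 1,
                            dimnames = list("envelope", NULL)), env$fs_hz)
}

#' Nominal beat and meter frequencies for a tempo
#'
#' @param bpm Tempo in beats per minute; 180 bpm gives the 3 Hz beat used with
#'   a 333 ms inter-onset interval, with duple 1.5 Hz, triple 1 Hz and
#'   quadruple 0.75 Hz groupings.
#' @return List with `beat_hz`, `duple_hz`, `triple_hz`, `quadruple_hz` and
#'   `pattern_hz` per pattern length (beat over the slot count is left to the
#'   caller; `pattern_hz` is `NULL` unless `n_slots` is given).
#' @param n_slots Optional beat-slot count of a pattern, to also report the
#'   whole-pattern repetition rate.
#' @export
nominal_frequencies <- function(bpm, n_slots = NULL) {
  if (!is.numeric(bpm) || bpm <= 0) stop("bpm must be positive")
  beat <- bpm / 60
  list(beat_hz = beat, duple_hz = beat / 2, triple_hz = beat / 3,
       quadruple_hz = beat / 4,
       pattern_hz = if (is.null(n_slots)) NULL else beat / n_slots)
}

#' Experiment schedule arithmetic
#'
#' Blocks of consecutive identical trials separated by silence; the default
#' session layout is 2 blocks of 25 trials per rhythm.
#'
#' @param trial_duration_s Duration of one trial in seconds.
#' @param trials_per_block,blocks_per_rhythm Block layout.
#' @param interblock_silence_s Silence between blocks, seconds.
#' @param baseline_silence_s Initial silent baseline, seconds.
#' @return Object of class `experiment_schedule` with per-block duration,
#'   total trial count and total stimulation time.
#' @export
build_schedule <- function(trial_duration_s, trials_per_block = 25,
                           blocks_per_rhythm = 2, interblock_silence_s = 30,
                           baseline_silence_s = 20 * 60) {
  stopifnot(trial_duration_s > 0, trials_per_block >= 1, blocks_per_rhythm >= 1)
  structure(list(
    trial_duration_s = trial_duration_s,
    trials_per_block = as.integer(trials_per_block),
    blocks_per_rhythm = as.integer(blocks_per_rhythm),
    interblock_silence_s = interblock_silence_s,
    baseline_silence_s = baseline_silence_s,
    block_duration_s = trials_per_block * trial_duration_s,
    total_trials = as.integer(trials_per_block * blocks_per_rhythm),
    total_stimulation_s = trials_per_block * blocks_per_rhythm * trial_duration_s),
    class = "experiment_schedule")
}

#' Write an envelope as a two-column TSV (time_s, amplitude)
#' @param env A `stimulus_envelope`.
#' @param path Output file.
#' @export
write_envelope_tsv <- function(env, path) {
  stopifnot(inherits(env, "stimulus_envelope"))
  d <- data.frame(time_s = seq_along(env$samples) / env$fs_hz,
                  amplitude = env$samples)
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Minimal 16-bit PCM mono WAV writer
#'
#' @param samples Numeric vector in [-1, 1] (clipped otherwise).
#' @param fs_hz Sampling rate.
#' @param path Output file.
#' @export
write_wav <- function(samples, fs_hz, path) {
  x <- pmin(1, pmax(-1, samples))
  pcm <- as.integer(round(x * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  n_bytes <- length(pcm) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")            # PCM
  writeBin(1L, con, size = 2, endian = "little")            # mono
  writeBin(as.integer(fs_hz), con, size = 4, endian = "little")
  writeBin(as.integer(fs_hz * 2), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}
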