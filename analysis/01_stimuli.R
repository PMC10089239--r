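#!/usr/bin/env Rscript
# Stimulus construction and paradigm arithmetic.
#
# Builds the two rhythmic patterns (six-beat "duple/triple" and twelve-beat
# "quadruple", 333 ms inter-onset interval, 180 bpm), renders their temporal
# envelopes, and verifies the paradigm arithmetic: pattern durations of
# 1.998 s and 3.996 s, 38 s / 36 s trials, 25-trial blocks of 950 s / 900 s,
# 50 trials per rhythm, and beat/meter frequencies of 3 / 1.5 / 1 / 0.75 Hz.
# Writes envelopes, spectra and audio renderings under results/stimuli/.

library(rhythmtag)

out_dir <- "results/stimuli"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

for (rhythm in c("duple_triple", "quadruple")) {
  spec1 <- if (rhythm == "duple_triple") duple_triple_rhythm(n_repetitions = 1)
  else quadruple_rhythm(n_repetitions = 1)
  full <- if (rhythm == "duple_triple") duple_triple_rhythm()
  else quadruple_rhythm()

  pattern <- build_rhythm(spec1, 1000)
  trial <- build_rhythm(full, 1000)
  cat(sprintf("%s: %d-slot pattern of %.3f s, %d repetitions -> %.3f s trials\n",
              rhythm, length(spec1$onset_pattern), pattern$duration_s,
              full$n_repetitions, trial$duration_s))

  sched <- build_schedule(round(trial$duration_s))
  cat(sprintf("  blocks: %d x %d trials = %g s per block, %d trials total\n",
              sched$blocks_per_rhythm, sched$trials_per_block,
              sched$block_duration_s, sched$total_trials))

  sp <- envelope_spectrum(trial)
  low <- sp$freqs_hz > 0.2 & sp$freqs_hz <= 3.2
  peaks <- sp$freqs_hz[low][sp$amps[1, low] > 0.02]
  cat(sprintf("  envelope peaks up to the beat: %s Hz\n",
              paste(round(peaks, 3), collapse = ", ")))

  write_envelope_tsv(trial, file.path(out_dir, paste0(rhythm, "_envelope.tsv")))
  write_wav(trial$samples / max(trial$samples), 1000,
            file.path(out_dir, paste0(rhythm, "_envelope.wav")))
  sp_tab <- data.frame(freq_hz = sp$freqs_hz[low], amplitude = sp$amps[1, low])
  write.table(sp_tab, file.path(out_dir, paste0(rhythm, "_envelope_spectrum.tsv")),
              sep = "\t", row.names = FALSE, quote = FALSE)
}

nf <- nominal_frequencies(180, n_slots = 6)
cat(sprintf("180 bpm -> beat %g Hz; duple %g, triple %g, quadruple %g Hz\n",
            nf$beat_hz, nf$duple_hz, nf$triple_hz, nf$quadruple_hz))
cat(sprintf("36 s trials -> spectral resolution %.4f Hz (printed 0.028)\n",
            1 / 36))
cat("outputs in", out_dir, "\n")
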