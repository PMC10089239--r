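# rhythmtag

Frequency-tagged EEG analysis of neural entrainment to auditory beat and
meter, with a ground-truth synthetic cohort generator for end-to-end
validation.

## What this solves, and for whom

When a rhythm built from 333 ms tones and rests (180 bpm) is played to a
listener, stimulus-locked neural activity shows up in the EEG spectrum as
steady-state evoked potentials: peaks at the 3 Hz beat and at the meter
rates formed by grouping beats in twos (1.5 Hz), threes (1 Hz) or fours
(0.75 Hz). This package is for EEG researchers — in particular those
working with developmental and neonatal recordings — who need the full
analysis chain for such experiments:

* **stimulus**: construction of cyclic tone/rest patterns, Hilbert
  amplitude envelopes, envelope spectra and session schedules;
* **preprocess**: zero-phase 0.5–45 Hz FIR band-pass (6 s of taps), 50 Hz
  notch, anti-aliased resampling to 512 Hz, outer-ring electrode removal,
  trial segmentation, 30 µV mean-amplitude channel/trial rejection with a
  >50% trial-drop rule, 100 µV artifact blocking, average reference;
* **freqtag**: trial averaging, DFT amplitude spectra (`2|X|/N`, so a unit
  sinusoid reads 1 µV), neighbour-bin noise subtraction (−5..−3 and +3..+5
  bins), all-scalp averaging, paired t tests of beat/meter amplitudes
  against the unrelated-frequency noise floor with Bonferroni correction
  and Cohen's d, and beat-normalised EEG-vs-stimulus enhancement tests;
* **sync**: Morlet wavelet phases (7 cycles, 2 ms steps), edge trimming,
  the complex synchronization index
  `SI(f) = (1/N) Σ_t exp(i[θ_EEG(t,f) − θ_stim(t,f)])`
  whose modulus is locking strength and angle the brain–stimulus lag, and
  Rayleigh tests of lag consistency across participants per electrode;
* **synthetic**: deterministic cohorts of multi-channel EEG with known
  SSEP amplitudes, envelope-locked phases, von Mises between-participant
  lags, 1/f noise and optional transients — the recovery target that makes
  every stage testable without access to restricted recordings.

## Worked example

A small synthetic cohort (5 participants, 10 trials of a six-beat rhythm,
8 channels) analysed end-to-end:

```r
library(rhythmtag)
cfg <- pipeline_config(rhythms = "duple_triple", n_channels = 8, fs_hz = 125,
                       n_trials = 10, n_participants = 5,
                       n_repetitions = list(duple_triple = 5, quadruple = 3),
                       window_bins = c(2, 3), noise_rms_uv = 5,
                       trim_s = list(duple_triple = 2, quadruple = 2),
                       sync_freqs_hz = list(duple_triple = c(1.5, 3),
                                            quadruple = c(0.75, 3)),
                       seed = 42)
res <- run_pipeline(cfg)
report(res)
```

```
== duple_triple rhythm ==
spectral resolution: 0.1001 Hz; participants: 5

Amplitude vs noise floor (scalp average, noise-subtracted):
 freq_hz mean_diff     t df    p_raw p_bonferroni cohens_d degenerate
     1.0    0.1671  4.33  4 1.24e-02     6.18e-02     1.94      FALSE
     1.5    0.2396  8.81  4 9.14e-04     4.57e-03     3.94      FALSE
     2.0    0.0854  5.93  4 4.05e-03     2.02e-02     2.65      FALSE
     2.5    0.0801  3.12  4 3.55e-02     1.77e-01     1.40      FALSE
     3.0    0.4715 23.77  4 1.86e-05     9.28e-05    10.63      FALSE

Beat-normalised EEG vs stimulus envelope at meter frequencies:
 freq_hz stim_value mean_eeg     t df       p cohens_d degenerate
     1.0      0.383   0.2526 -2.06  4 0.10798   -0.923      FALSE
     1.5      0.333   0.4368  1.87  4 0.13478    0.836      FALSE
     2.0      0.280   0.0524 -7.39  4 0.00179   -3.304      FALSE
     2.5      0.228   0.0405 -5.51  4 0.00528   -2.466      FALSE

Brain-stimulus synchronization (Rayleigh p < 0.05 per electrode):
 freq_hz n_electrodes n_significant mean_strength group_angle_deg
     1.5            8             1         0.650          -136.1
     3.0            8             6         0.726            78.8
```

Reading it: the generator injects 0.3 µV components at 1 and 1.5 Hz and
0.5 µV at 3 Hz over 5 µV 1/f noise. The first table shows the
noise-subtracted scalp-average amplitude at each stimulus-related frequency
against the per-participant noise floor — at this small cohort size the
beat and duple-meter peaks already survive Bonferroni correction. The
second table compares beat-normalised EEG amplitudes with the stimulus
envelope's (the EEG meter/beat ratio at 1.5 Hz, 0.44, exceeds the
envelope's 0.33 — the injected enhancement — but 5 participants give little
power). The third summarises locking: modulus of the mean SI per electrode
and how many electrodes show participant-consistent lags; the group angle
recovers the injected lags (−126° at 1.5 Hz, +46° at 3 Hz, here estimated
from 5 participants' von Mises draws).

The numbered drivers under `analysis/` run the full studies and write
their tables under `results/`: `01_stimuli.R` (paradigm arithmetic and
envelope spectra), `02_cohort_study.R` (the 17-participant study-like
cohort), `03_recovery.R` (quantitative ground-truth recovery), and
`04_preprocessing_check.R` (filter responses and chain stability).

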