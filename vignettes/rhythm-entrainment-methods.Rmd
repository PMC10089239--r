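---
title: "Frequency-tagged analysis of neural entrainment to auditory beat and meter"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frequency-tagged analysis of neural entrainment to auditory beat and meter}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(rhythmtag)
```

## The problem

When a periodic auditory rhythm is played to a listener, neural activity
phase-locked to the stimulus appears in the EEG as steady-state evoked
potentials (SSEPs): narrow spectral peaks at the stimulation-related
frequencies. For a rhythm built from 333 ms beat slots (180 bpm), the beat
sits at 3 Hz and perceptual groupings of two, three or four beats — duple,
triple and quadruple meter — correspond to 1.5, 1 and 0.75 Hz. Comparing
peak amplitudes at these frequencies against the surrounding spectral noise,
and comparing beat-normalised EEG amplitudes against the stimulus envelope's
own spectrum, asks whether the brain merely follows the acoustics or
selectively enhances metrical levels. A complementary phase analysis asks
whether the neural oscillation maintains a consistent lag behind the
stimulus envelope.

`rhythmtag` implements this analysis chain end-to-end and — because consent
restrictions preclude sharing the neonatal recordings this methodology was
built for — pairs it with a synthetic EEG cohort generator with known ground
truth, so every stage is testable and the whole pipeline's recovery
behaviour can be quantified.

## Stimuli

Two cyclic patterns of sounded and silent 333 ms slots are built in:
a six-slot cycle (1.998 s, repeated 19 times for ~38 s trials), metrically
ambiguous between duple and triple grouping, and a twelve-slot cycle
(3.996 s, repeated 9 times for ~36 s trials) with a quadruple grouping.
The published patterns are shown only graphically in the source material,
so the built-in sounded/silent assignments are reconstructions; any pattern
of the right length can be supplied through `rhythm_spec()`. Tones are
percussive bursts (5 ms linear attack, 100 ms exponential decay, truncated
at the slot boundary); timbre is irrelevant to envelope periodicity, which
is all the frequency-tagging analysis sees. `hilbert_envelope()` extracts
amplitude envelopes of arbitrary audio via the analytic signal;
`envelope_spectrum()` uses one full trial so that, with an integer number of
pattern cycles, every envelope harmonic falls on an exact DFT bin.

A deliberate dialect note: with a 333 ms inter-onset interval the "3 Hz"
beat actually sits at 3.003 Hz (the 6th harmonic of the 0.5005 Hz pattern
rate). All frequency read-outs therefore use nearest-bin lookup rather than
exact equality, which absorbs this 0.1% discrepancy; a warning fires only
when a requested frequency lies beyond the spectrum's grid.

## Preprocessing

The chain mirrors standard dense-array infant EEG practice, in order:

* **Band-pass 0.5–45 Hz**, two-pass (forward–backward, hence zero-phase)
  windowed-sinc FIR whose length is three cycles of the low cutoff (6 s of
  taps). Two passes of a linear-phase FIR equal filtering with the squared
  magnitude response and no phase shift, so the filter is applied in the
  frequency domain on a reflection-padded FFT grid — identical output,
  far cheaper than time-domain convolution with 6 s of taps. The measured
  two-pass gain is 1.000 at 1–3 Hz and 0.994 at 0.75 Hz (the transition
  band reaches the quadruple-meter frequency; `analysis/04_preprocessing_check.R`
  prints the full response).
* **50 Hz notch** (band-stop FIR, same zero-phase application): ≥ 40 dB
  at the line frequency, neighbours ±2 Hz preserved within ~0.2%.
* **Resampling to 512 Hz** by Fourier-domain truncation at the new Nyquist
  frequency — an ideal anti-aliasing filter with exactly unit passband gain.
  (A polyphase resampler was tried first and rejected after measuring a 2%
  passband gain error.)
* **Outer-ring removal** by explicit keep-list (the published 124-channel
  geometry is not reproduced here; the synthetic generator uses a generic
  grid, so the keep-list is the user's responsibility on real data).
* **Segmentation** at stimulus onsets, then **amplitude rejection**: a
  channel is marked within a trial when its mean absolute amplitude exceeds
  30 µV, and a trial is discarded when more than 50% of channels are
  marked. The 30 µV criterion is applied after downsampling, following the
  order in which the steps are described. Losing every trial raises a
  `participant_excluded` condition. Visual inspection is not automatable
  and is deliberately replaced by these amplitude criteria alone.
* **Artifact blocking** at 100 µV: a simplified variant of the
  reference-matrix artifact-blocking approach. A reference copy of each
  trial is clipped at the threshold and the spatial operator `B` minimising
  the squared error to the reference is solved in closed form
  (`B = X_ref X' (X X' + eps I)^-1`) and applied; residual overshoot is
  clipped. Trials with no supra-threshold sample pass through untouched.
  This is documented as an approximation, not a reimplementation, of the
  published algorithm.
* **Average reference** (exactly zero channel mean per sample, idempotent).

One structural consequence is worth stating plainly: average referencing
removes the spatial mean of any signal, so a steady-state component whose
channel topography has non-zero mean is attenuated by re-referencing. The
generator's smooth random topographies are normalised to mean 1 (so the
scalp-averaged spectrum reads the injected amplitude directly), which makes
them maximally vulnerable to that subtraction. Quantitative amplitude
recovery is therefore assessed on directly segmented synthetic trials,
while the preprocessing chain is validated separately on inputs with
zero-mean topography, where its target-bin gain is within 1% (see
`analysis/04_preprocessing_check.R` and the chain test).

## Frequency tagging

Kept trials are averaged per channel (respecting the rejection mask), the
averaged waveform is Fourier-transformed, and amplitudes use the `2|X|/N`
convention so a unit-amplitude sinusoid spanning whole cycles reads
1.0 µV; the source material never states its normalisation, and this choice
makes injected amplitudes directly readable. A 36 s trial gives the
0.0278 Hz resolution printed as 0.028 Hz.

Residual background noise is removed per bin by subtracting the mean
amplitude at the surrounding bins −5..−3 and +3..+5 (±0.07–0.15 Hz at
0.028 Hz resolution), leaving a one-bin guard. Corrected values may be
negative and are not floored — flooring would bias every comparison against
the noise floor upward. Edge bins lacking the full neighbour set are
flagged and excluded.

Spectra are averaged over all retained scalp electrodes (no electrode
selection), target amplitudes are read at the stimulus-related frequencies
(1, 1.5, 2, 2.5, 3 Hz for the six-beat rhythm; 0.75–3 Hz in 0.25 Hz steps
for the twelve-beat rhythm; 0.25/0.5 Hz are excluded because of the 0.5 Hz
high-pass), and the noise floor is the mean over the interleaved unrelated
sets. Group statistics are paired t tests of each related frequency against
the per-participant noise floor, Bonferroni-corrected over the related set,
with paired Cohen's d; zero-variance differences are flagged rather than
silently producing NaN. Enhancement is tested by normalising each
participant's amplitudes by the 3 Hz beat amplitude and comparing the
meter frequencies against the identically normalised stimulus envelope
spectrum.

### The estimator's amplitude bias, and how recovery is tested

Neighbour-bin subtraction operates on amplitude (not power) spectra. At a
signal bin the expected amplitude is `sqrt(S^2 + sigma^2)` while the
neighbour mean estimates `E|N| = 0.886 sigma` (`sigma` = per-bin complex
noise SD after trial averaging), so the corrected value has expectation
about `S - 0.886 sigma + sigma^2 / 2S`: a negative bias, first order in
`sigma`. This is intrinsic to the method, not an implementation artifact.
Under the study-like noise model (10 µV RMS 1/f noise, 50 trials,
≤ 38 s trials) `sigma` at 1–1.5 Hz is of order 0.1 µV, so 0.3 µV components
read 20–35% low — and no channel count can repair this, because electrode
averaging of amplitude spectra reduces the variance of `E|N|`, not its
mean (which is precisely why the subtraction step exists).

The package therefore validates amplitude recovery where the estimator is
designed to operate. The recovery cohort (`recovery_study_config()`) keeps
the study's structure — 17 participants, 50 trials, von Mises κ = 5 — and
sets the background noise to 1.5 µV RMS, chosen once from the closed-form
budget `0.886 sigma ≤ 5%` of a 0.3 µV component before the recovery test
was first run. On that cohort all five injected components recover within
10% (typical errors −2% at the beat, −6 to −9% at the meters, the residual
being exactly the bias above) and all group-mean lags within a fraction of
a degree. The study-like cohort (`scaled_study_config()`, 10 µV noise)
keeps the claims that are robust to the bias: every injected beat/meter
frequency sits far above the noise floor at group level, and phase lags
recover to better than 1° — phase quantities are untouched by the
amplitude bias.

## Brain–stimulus synchronization

Time–frequency phases come from Morlet wavelets of seven cycles, sampled
every 2 ms (snapped to the sample grid) — implemented by FFT convolution
with unit-energy wavelets, zero-padded beyond the wavelet half-width. The
first and last 2 s of each six-beat-rhythm trial (4 s for the twelve-beat
rhythm) are trimmed. Complex coefficients are normalised to unit magnitude
per trial, averaged across trials, and the phase of the average is taken;
the documented alternative (extract the phase per trial, then average the
unit phasors) is available in `phase_series()` and coincides exactly with
the default for magnitude-normalised coefficients. The stimulus envelope
goes through the identical wavelet pathway, so analysis-filter delays
cancel in the phase difference.

The synchronization index per electrode and frequency is the time average
of the unit phasor of the phase difference,
`SI(f) = (1/N) sum_t exp(i (theta_EEG(t,f) - theta_stim(t,f)))`, with `N`
the retained time points after trimming; `|SI|` ∈ [0, 1] is the locking
strength and `Arg(SI)` the lag. Consistency of lags across participants is
tested per electrode with the Rayleigh test (`z = n R^2`, small-sample
p-approximation `exp(sqrt(1 + 4n + 4(n^2 - (nR)^2)) - (1 + 2n))`), whose
agreement with a brute-force uniform-null simulation is itself a test in
the suite.

Two cautions established on synthetic data: `|SI|` is upward-biased when
the analysis window holds few independent coefficient samples (the wavelet
correlation time at 0.75 Hz is ~1.5 s), so locking strengths should not be
compared across frequencies without matching window lengths; recovery
*precision* is the right cross-frequency quantity, and with matched
in-band SNR (1/f noise) the recovered lag scatters about twice as much at
0.75 Hz as at 3 Hz over fixed-length trials — the slow-meter falloff the
analysis is designed to exhibit.

## The synthetic cohort generator

Each participant's EEG is a sum of steady-state sinusoids — one per
component, at the envelope harmonic nearest the nominal frequency, with
phase equal to the envelope's own DFT phase at that harmonic plus the
participant's lag — weighted by a smooth random channel topography of mean
1, plus independent 1/f (`pink_noise()`) background per channel and trial,
plus optional Gaussian-shaped transients. Participant lags are drawn von
Mises around each component's group lag with concentration κ. Everything
is deterministic given the seed.

Defaults emulate the study conditions: 98 channels at 1000 Hz, 50 trials
per rhythm, 17 participants (19 recorded minus 2 excluded), 0.3 µV
components at meter frequencies and 0.5 µV at the beat (neonatal SSEP
amplitudes are not printed anywhere; these are order-of-magnitude choices),
10 µV RMS noise with exponent 1, κ = 5. What the generator deliberately
does **not** emulate: convolved event-related responses (components are
steady-state sinusoids, sufficient for bin-level and phase-level
assertions), neonatal EEG microstructure (tracé alternant, delta brushes),
the real sensor geometry, or non-stationary artifacts beyond simple
transients. Consequently, passing tests demonstrate the correctness and
calibration of the analysis chain — not that real neonatal data would meet
any particular effect size.

## Problem sizes used by the drivers and the validation suite

Full-scale cohorts (98 × 1000 Hz × 38 s × 50 × 17, twice) are ~1.5 GB per
participant and serve no inferential purpose in validation, so the
package's own studies run reduced cohorts, chosen once:

* `scaled_study_config()` — the study-like stand-in: 48 channels, 250 Hz,
  10 six-beat / 5 twelve-beat pattern repeats per trial (~20 s), 50 trials,
  17 participants, 10 µV noise, κ = 5.
* `recovery_study_config()` — quantitative recovery: as above with 16
  channels and 1.5 µV noise (bias budget above).

At the coarser 0.05 Hz resolution of ~20 s trials, the ±3..5-bin window
would span ±0.15–0.25 Hz and let stimulus harmonics 0.25 Hz apart
contaminate each other's noise estimates, so these configurations use
±2..3 bins (±0.10–0.15 Hz), inside the physical span of the full-length
window. `window_bins` remains ±3..5 by default for full-length trials.

A consequence of synthetic group power worth knowing: with 17 clean
participants the paired t against the noise floor resolves systematic
offsets of ~0.02 µV, so non-injected stimulus-related bins can reach
nominal significance through the curvature of the 1/f noise amplitude
across the related/unrelated frequency sets. Real data are far noisier;
the suite only asserts detection at injected components.

## Numerical and design choices, collected

* Nearest-bin frequency lookup everywhere; mismatch warning only beyond
  the grid.
* DFT amplitude convention `2|X|/N`; negative corrected amplitudes kept.
* Bonferroni family = related set per rhythm (5 and 10).
* Degenerate zero-variance contrasts flagged (`degenerate`), with p = 0 or
  1 and infinite d, instead of NaN.
* FFT lengths are padded to highly composite sizes; wavelets are
  unit-energy; zero-phase filtering uses reflection padding of one filter
  length.
* Seeds: one master seed; per-participant and per-rhythm seeds derived by
  a fixed integer mix kept inside 32-bit range.
* EDF and WAV writers are minimal in-package implementations (16-bit), and
  EDF round-trips are tested against the quantisation step.

## Limitations

The artifact-blocking step is an acknowledged simplification of the cited
algorithm. The built-in onset patterns are reconstructions. The generator's
SSEPs are stationary sinusoids, so the pipeline's behaviour under
non-stationary entrainment is untested. The published infant-group
statistics and mean phase angles are not reproduction targets anywhere in
this package, since the underlying recordings are not publicly available.
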