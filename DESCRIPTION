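Package: rhythmtag
Title: Frequency-Tagged EEG Analysis of Neural Entrainment to Auditory Beat and Meter
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse steady-state evoked potentials elicited by rhythmic
    auditory stimulation, as used to study beat and meter tracking in the premature
    neonate brain. Provides construction of rhythmic stimulus envelopes and their
    spectra, an EEG preprocessing chain (zero-phase FIR band-pass and notch
    filtering, resampling, amplitude-based channel/trial rejection, artifact
    blocking, average reference), frequency-tagging spectral analysis with
    neighbour-bin noise subtraction and group enhancement statistics, Morlet-wavelet
    phase extraction with a complex brain-stimulus synchronization index and
    Rayleigh circular tests, and a ground-truth synthetic EEG cohort generator for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
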