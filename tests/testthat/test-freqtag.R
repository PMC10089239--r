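# Frequency tagging: averaging, spectra, noise subtraction, target
# extraction, group statistics, beat normalisation.

test_that("trial averaging respects the rejection mask", {
  x <- array(0, dim = c(2, 3, 40))
  x[1, , ] <- rep(sin(seq_len(40)), each = 3)
  x[2, , ] <- x[1, , ]
  ts <- make_trial_set(x, 100)
  expect_equal(average_trials(ts), x[1, , ],
               ignore_attr = TRUE)
  # trial plus its negation averages to zero
  x[2, , ] <- -x[1, , ]
  expect_equal(max(abs(average_trials(make_trial_set(x, 100)))), 0)
  # masked trials do not contribute
  ts2 <- make_trial_set(x, 100)
  ts2$kept_mask[2, 1] <- FALSE
  avg <- average_trials(ts2)
  expect_equal(avg[1, ], x[1, 1, ])
  expect_equal(avg[2, ], rep(0, 40))
})

test_that("trial averaging improves target-bin SNR roughly as sqrt(n)", {
  fs <- 125; n_tr <- 25
  n <- 8 * fs
  t <- seq_len(n) / fs
  set.seed(21)
  sig <- 0.5 * cos(2 * pi * 3 * t)
  trials <- array(NA_real_, dim = c(n_tr, 1, n))
  for (i in seq_len(n_tr)) trials[i, 1, ] <- sig + pink_noise(n, 1, 5)
  avg <- average_trials(make_trial_set(trials, fs))
  noise_rms <- function(x) {
    sp <- amplitude_spectrum(x, fs)
    band <- sp$freqs_hz > 2 & sp$freqs_hz < 4 &
      abs(sp$freqs_hz - 3) > 3 * sp$resolution_hz
    sqrt(mean(sp$amps[1, band]^2))
  }
  ratio <- noise_rms(trials[1, 1, ]) / noise_rms(avg[1, ])
  expect_gt(ratio, sqrt(n_tr) * 0.6)
  expect_lt(ratio, sqrt(n_tr) * 1.6)
})

test_that("amplitude spectra use the unit-sinusoid convention and 1/T resolution", {
  fs <- 512
  # 36 s trial -> 0.0278 Hz resolution (printed 0.028)
  sp36 <- amplitude_spectrum(rnorm(36 * fs), fs)
  expect_equal(sp36$resolution_hz, 1 / 36)
  expect_equal(round(sp36$resolution_hz, 3), 0.028)
  t <- seq_len(8 * fs) / fs
  sp <- amplitude_spectrum(cos(2 * pi * 3 * t), fs)
  expect_equal(sp$amps[1, which.min(abs(sp$freqs_hz - 3))], 1,
               tolerance = 1e-10)
  # two sinusoids -> two bins, closed form
  x <- 2 * cos(2 * pi * 1.5 * t) + 0.25 * cos(2 * pi * 5 * t + 0.9)
  sp2 <- amplitude_spectrum(x, fs)
  expect_equal(sp2$amps[1, which.min(abs(sp2$freqs_hz - 1.5))], 2,
               tolerance = 1e-10)
  expect_equal(sp2$amps[1, which.min(abs(sp2$freqs_hz - 5))], 0.25,
               tolerance = 1e-10)
  others <- setdiff(seq_along(sp2$freqs_hz),
                    c(which.min(abs(sp2$freqs_hz - 1.5)),
                      which.min(abs(sp2$freqs_hz - 5))))
  expect_lt(max(sp2$amps[1, others]), 1e-10)
})

test_that("neighbour-bin subtraction matches the hand-computed oracle", {
  sp <- make_spectrum(c(1, 1, 1, 0, 0, 10, 0, 0, 1, 1, 1))
  ns <- noise_subtract(sp, c(3, 5))
  expect_equal(ns$amps[1, 6], 10 - mean(c(1, 1, 1, 1, 1, 1)))
  # flat spectrum -> all zeros (where the window fits)
  flat <- noise_subtract(make_spectrum(rep(4, 20)))
  expect_equal(unname(flat$amps[1, !flat$edge_flag]),
               rep(0, sum(!flat$edge_flag)))
  # edge bins are flagged and excluded
  expect_true(all(flat$edge_flag[1:5]))
  expect_true(all(is.na(flat$amps[1, flat$edge_flag])))
})

test_that("neighbour-bin subtraction is shift-equivariant and centred on noise", {
  set.seed(31)
  a <- abs(rnorm(60))
  base <- noise_subtract(make_spectrum(a))
  shifted <- noise_subtract(make_spectrum(a + 7))
  expect_equal(base$amps, shifted$amps)
  # corrected white-noise values average to ~0
  set.seed(32)
  vals <- replicate(40, {
    ns <- noise_subtract(make_spectrum(abs(rnorm(200, 1, 0.2))))
    mean(ns$amps[1, !ns$edge_flag])
  })
  expect_lt(abs(mean(vals)), 3 * sd(vals) / sqrt(length(vals)) + 0.01)
})

test_that("scalp averaging equals the brute-force electrode mean", {
  set.seed(41)
  amps <- matrix(abs(rnorm(5 * 30)), 5, 30)
  sp <- structure(list(freqs_hz = 0:29, amps = amps, resolution_hz = 1,
                       fs_hz = 60, channel_labels = paste0("E", 1:5)),
                  class = "amplitude_spectrum")
  expect_equal(scalp_average(sp)$amps[1, ], colMeans(amps))
  sp$amps <- rbind(amps[1, ], amps[1, ])
  expect_equal(scalp_average(sp)$amps[1, ], amps[1, ])
  sp$amps <- rbind(amps[1, ], -amps[1, ])
  expect_equal(max(abs(scalp_average(sp)$amps)), 0)
})

test_that("target sets are disjoint, above the high-pass cutoff, and extracted by nearest bin", {
  for (r in c("duple_triple", "quadruple")) {
    s <- target_frequency_sets(r)
    expect_length(intersect(s$related_hz, s$unrelated_hz), 0)
    expect_true(all(c(s$related_hz, s$unrelated_hz) > 0.5))
  }
  s <- target_frequency_sets("duple_triple")
  expect_equal(s$related_hz, c(1, 1.5, 2, 2.5, 3))
  expect_equal(s$unrelated_hz, c(0.75, 1.25, 1.75, 2.25, 2.75))
  sq <- target_frequency_sets("quadruple")
  expect_length(sq$related_hz, 10)
  expect_length(sq$unrelated_hz, 10)
  # extraction: amplitude only at 1.5 Hz -> duple read-out 1, noise floor 0
  amps <- rep(0, 81)
  res_hz <- 0.05
  amps[1.5 / res_hz + 1] <- 1
  ext <- extract_target_amplitudes(make_spectrum(amps, res_hz), s)
  expect_equal(unname(ext$related["1.5"]), 1)
  expect_equal(ext$noise_floor, 0)
  # uniform spectrum: every target c, floor c
  extc <- extract_target_amplitudes(make_spectrum(rep(0.7, 81), res_hz), s)
  expect_true(all(extc$related == 0.7))
  expect_equal(extc$noise_floor, 0.7)
  # random spectrum matches a brute-force lookup
  set.seed(51)
  a <- abs(rnorm(81))
  extr <- extract_target_amplitudes(make_spectrum(a, res_hz), s)
  brute <- a[vapply(s$related_hz,
                    function(f) which.min(abs((0:80) * res_hz - f)), 1L)]
  expect_equal(unname(extr$related), brute)
})

test_that("frequencies beyond the bin grid trigger a mismatch warning", {
  # within the grid the nearest bin is always within half a bin; only a
  # target beyond the spectrum's reach can exceed the tolerance
  s <- list(related_hz = 7, unrelated_hz = 2)
  expect_warning(extract_target_amplitudes(make_spectrum(rep(1, 10), 0.5), s),
                 "nearest bin")
})

test_that("group test matches the textbook paired-t oracle", {
  # diffs 1..5: t = 3/(sd/sqrt(5)), d = 3/sd
  amps <- matrix(c(1, 2, 3, 4, 5), ncol = 1, dimnames = list(NULL, "3"))
  res <- group_test(amps, rep(0, 5))
  expect_equal(res$t, 3 / (sd(1:5) / sqrt(5)), tolerance = 1e-12)
  expect_equal(res$t, 4.2426, tolerance = 1e-4)
  expect_equal(res$cohens_d, 1.8974, tolerance = 1e-4)
  expect_equal(res$df, 4)
  # Bonferroni over the related family
  amps3 <- cbind(`1` = 1:6, `2` = 6:1, `3` = c(2, 4, 3, 5, 4, 6))
  res3 <- group_test(amps3, rep(0, 6))
  expect_equal(res3$p_bonferroni, pmin(1, res3$p_raw * 3))
  # degenerate and null cases
  resd <- group_test(matrix(rep(2, 4), ncol = 1), rep(1, 4))
  expect_true(resd$degenerate)
  expect_equal(resd$p_raw, 0)
  res0 <- group_test(matrix(c(-1, 1, -2, 2), ncol = 1), rep(0, 4))
  expect_equal(res0$t, 0, tolerance = 1e-12)
  expect_equal(res0$p_bonferroni, 1)
  expect_error(group_test(matrix(1, 1, 1), 0), "participants")
})

test_that("beat normalisation maps the beat to 1 and scales meters", {
  amps <- c(`1` = 0.2, `1.5` = 0.4, `3` = 0.4)
  norm <- normalize_by_beat(amps)
  expect_equal(unname(norm["3"]), 1)
  expect_equal(unname(norm["1.5"]), 1)
  expect_equal(unname(norm["1"]), 0.5)
  expect_error(normalize_by_beat(c(`1` = 1, `3` = 0)), "> 0")
  expect_error(normalize_by_beat(c(`1` = 1, `2` = 2)), "not present")
})

test_that("EEG vs stimulus comparison recovers a simulated enhancement", {
  # all participants equal to the stimulus -> t = 0
  eeg <- matrix(0.4, 6, 1, dimnames = list(NULL, "1.5"))
  res <- compare_eeg_vs_stimulus(eeg, c(`1.5` = 0.4))
  expect_equal(res$t, 0)
  expect_true(res$degenerate)
  # constant offset -> infinite d, flagged
  res2 <- compare_eeg_vs_stimulus(eeg + 0.1, c(`1.5` = 0.4))
  expect_true(res2$degenerate)
  expect_equal(res2$cohens_d, Inf)
  # simulated enhancement delta with noise sigma, n = 17
  set.seed(61)
  delta <- 0.12; sigma <- 0.05; n <- 17
  tvals <- replicate(200, {
    x <- matrix(0.4 + delta + rnorm(n, sd = sigma), ncol = 1,
                dimnames = list(NULL, "1.5"))
    compare_eeg_vs_stimulus(x, c(`1.5` = 0.4))$t
  })
  expect_equal(mean(tvals), delta / (sigma / sqrt(n)), tolerance = 0.1)
})
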