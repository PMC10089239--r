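# Preprocessing chain: filters, resampling, rejection, artifact blocking,
# referencing, and the order-stability of the whole chain.

test_that("band-pass filter preserves the passband, removes drift and DC, zero phase", {
  fs <- 250
  t <- seq(0, 40 - 1 / fs, by = 1 / fs)
  x <- cos(2 * pi * 1 * t) + 0.5 * cos(2 * pi * 0.1 * t) + 2
  rec <- bandpass_filter(eeg_recording(rbind(x), fs))
  expect_equal(amp_at(rec$data[1, ], fs, 1), 1, tolerance = 0.05)
  expect_lt(amp_at(rec$data[1, ], fs, 0.1), 0.05)   # >10x attenuation
  expect_lt(abs(mean(rec$data[1, ])), 1e-3)          # DC removed
  # zero-phase: cross-correlation peak of a passband sinusoid at lag 0
  y <- bandpass_filter(eeg_recording(rbind(cos(2 * pi * 3 * t)), fs))$data[1, ]
  cc <- stats::ccf(y[2000:8000], cos(2 * pi * 3 * t)[2000:8000],
                   lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
  expect_error(bandpass_filter(eeg_recording(rbind(x), fs), 30, 20), "lo_hz")
  expect_error(bandpass_filter(eeg_recording(rbind(x[1:100]), fs)), "shorter")
})

test_that("notch filter removes line noise and spares neighbours", {
  fs <- 250
  t <- seq(0, 30 - 1 / fs, by = 1 / fs)
  x <- cos(2 * pi * 50 * t) + 0.5 * cos(2 * pi * 48 * t) +
    0.5 * cos(2 * pi * 52 * t) + 0.8 * cos(2 * pi * 3 * t)
  rec <- notch_filter(eeg_recording(rbind(x), fs))
  expect_lt(amp_at(rec$data[1, ], fs, 50), 0.1)           # >= 20 dB down
  expect_equal(amp_at(rec$data[1, ], fs, 48), 0.5, tolerance = 0.1)
  expect_equal(amp_at(rec$data[1, ], fs, 52), 0.5, tolerance = 0.1)
  expect_equal(amp_at(rec$data[1, ], fs, 3), 0.8, tolerance = 0.02)
  expect_error(notch_filter(eeg_recording(rbind(x), fs), line_hz = 200), "fs/2")
})

test_that("resampling preserves duration and passband amplitude", {
  fs <- 1000
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  rec <- resample_eeg(eeg_recording(rbind(cos(2 * pi * 3 * t)), fs), 512)
  expect_equal(ncol(rec$data), 5120)
  expect_equal(rec$fs_hz, 512)
  # spectral read-out over an integer-cycle core, away from edge transients
  core <- rec$data[1, 513:(512 + 4096)]  # 8 s at 512 Hz
  expect_equal(amp_at(core, 512, 3), 1, tolerance = 0.01)
  # identity at equal rate; error when upsampling requested
  rec0 <- eeg_recording(rbind(cos(2 * pi * 3 * t)), fs)
  expect_identical(resample_eeg(rec0, fs), rec0)
  expect_error(resample_eeg(rec0, 2000), "exceed")
})

test_that("channel subsetting keeps order and validates labels", {
  rec <- eeg_recording(matrix(seq_len(20), 4, 5),
                       100, c("A", "B", "C", "D"))
  out <- drop_outer_ring(rec, c("D", "B"))
  expect_equal(out$channel_labels, c("B", "D"))
  expect_equal(out$data, rec$data[c(2, 4), ])
  expect_identical(drop_outer_ring(rec, rec$channel_labels)$data, rec$data)
  expect_error(drop_outer_ring(rec, c("B", "Z")), "unknown")
})

test_that("amplitude rejection marks channels and drops trials by the >50% rule", {
  n_ch <- 98
  trials <- array(0, dim = c(3, n_ch, 100))
  trials[1, 1, ] <- 31          # marked (mean |x| = 31 > 30)
  trials[1, 2, ] <- 29          # kept
  trials[2, 1:50, ] <- 40       # 50/98 = 51% -> trial dropped
  res <- reject_channels_trials(make_trial_set(trials, 100))
  expect_equal(res$report$dropped_trials, 2L)
  expect_equal(res$report$n_trials_kept, 2L)
  expect_false(res$trials$kept_mask[1, 1])
  expect_true(res$trials$kept_mask[1, 2])
  # threshold monotonicity: a higher threshold never drops more trials
  set.seed(11)
  rnd <- array(rnorm(10 * 20 * 50, sd = 30), dim = c(10, 20, 50))
  ts <- make_trial_set(rnd, 100)
  dropped <- vapply(c(10, 20, 30, 40, 60),
                    function(th) {
                      r <- tryCatch(reject_channels_trials(ts, th),
                                    participant_excluded = function(e) NULL)
                      if (is.null(r)) dim(rnd)[1]
                      else length(r$report$dropped_trials)
                    }, 1)
  expect_true(all(diff(dropped) <= 0))
})

test_that("losing every trial raises a participant-excluded condition", {
  trials <- array(100, dim = c(2, 4, 50))
  expect_error(reject_channels_trials(make_trial_set(trials, 100)),
               class = "participant_excluded")
})

test_that("artifact blocking caps transients and leaves clean data alone", {
  fs <- 250
  t <- seq(0, 8 - 1 / fs, by = 1 / fs)
  clean <- rbind(20 * cos(2 * pi * 3 * t), 15 * cos(2 * pi * 1 * t + 1),
                 10 * cos(2 * pi * 1.5 * t), 80 * cos(2 * pi * 2 * t))
  ts_clean <- make_trial_set(array(clean, dim = c(1, 4, length(t))), fs)
  out <- artifact_block(ts_clean)
  expect_equal(out$trials, ts_clean$trials, tolerance = 1e-8)
  # transient on one channel gets capped...
  dirty <- clean
  dirty[2, 1000:1025] <- dirty[2, 1000:1025] + 500
  ts_dirty <- make_trial_set(array(dirty, dim = c(1, 4, length(t))), fs)
  blocked <- artifact_block(ts_dirty)
  expect_lte(max(abs(blocked$trials)), 100)
  # ...and the oscillatory content survives within 10% of the artifact-free run
  a_clean <- amp_at(ts_clean$trials[1, 1, ], fs, 3)
  a_blocked <- amp_at(blocked$trials[1, 1, ], fs, 3)
  expect_equal(a_blocked, a_clean, tolerance = 0.1)
})

test_that("average reference zeroes the channel mean and is idempotent", {
  set.seed(5)
  rec <- eeg_recording(matrix(rnorm(400), 8, 50), 100)
  ar <- average_reference(rec)
  expect_lt(max(abs(colMeans(ar$data))), 1e-12)
  expect_equal(average_reference(ar)$data, ar$data)
  # symmetric pair is untouched
  pair <- eeg_recording(rbind(sin(1:50), -sin(1:50)), 100)
  expect_equal(average_reference(pair)$data, pair$data)
  # trial_set method
  ts <- make_trial_set(array(rnorm(2 * 4 * 30), dim = c(2, 4, 30)), 100)
  art <- average_reference(ts)
  for (i in 1:2) expect_lt(max(abs(colMeans(art$trials[i, , ]))), 1e-12)
})

test_that("the full chain preserves steady-state target bins within 10%", {
  # zero-mean topography so average referencing is a no-op on the signal
  fs <- 250
  weights <- c(1.5, 0.5, -1, -1)
  rec <- make_sine_recording(c(1, 1.5, 3), c(2, 2, 2), weights, fs,
                             dur_s = 60, phases = c(0.3, 1.1, -0.7))
  res <- preprocess_chain(rec, onsets_s = seq(20, 44, by = 8),
                          trial_duration_s = 8, line_hz = NULL)
  avg <- average_trials(res$trials)
  for (f in c(1, 1.5, 3))
    for (ch in 1:4)
      expect_equal(amp_at(avg[ch, ], fs, f), 2 * abs(weights[ch]),
                   tolerance = 0.1)
})
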