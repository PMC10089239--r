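# Morlet phases, synchronization index, circular statistics.

test_that("Morlet phase advances at the analysed frequency and is selective", {
  fs <- 250
  t <- seq(0, 20 - 1 / fs, by = 1 / fs)
  tf <- trim_edges(morlet_tf(cos(2 * pi * 3 * t), fs, c(0.75, 3)), 4)
  ph <- Arg(tf$coef[2, ])
  unwrapped <- cumsum(c(ph[1], rhythmtag:::wrap_angle(diff(ph))))
  slope <- unname(coef(lm(unwrapped ~ tf$times_s))[2])
  expect_equal(slope, 2 * pi * 3, tolerance = 0.01 * 2 * pi * 3)
  # analysing a 3 Hz tone at 0.75 Hz picks up almost nothing
  expect_lt(mean(Mod(tf$coef[1, ])), 0.01 * mean(Mod(tf$coef[2, ])))
  # zero signal -> zero coefficients
  tf0 <- morlet_tf(rep(0, length(t)), fs, c(1, 3))
  expect_equal(max(Mod(tf0$coef)), 0)
  # too-short input rejected
  expect_error(morlet_tf(rep(1, fs), fs, 0.75), "cycles")
})

test_that("the 2 ms step at 512 Hz lands on the sample grid", {
  fs <- 512
  x <- cos(2 * pi * 3 * seq(0, 16, by = 1 / fs))
  tf <- morlet_tf(x, fs, 3)
  expect_equal(tf$step_s, 1 / fs)  # 2 ms rounds to one 512 Hz sample
})

test_that("edge trimming shortens the time axis symmetrically", {
  fs <- 100
  x <- cos(2 * pi * 3 * seq(0, 38 - 1 / fs, by = 1 / fs))
  tf <- morlet_tf(x, fs, 3, step_ms = 10)
  tr <- trim_edges(tf, 2)
  expect_equal(max(tf$times_s) - max(tr$times_s), 2, tolerance = 0.011)
  expect_equal(min(tr$times_s) - min(tf$times_s), 2, tolerance = 0.011)
  expect_identical(trim_edges(tf, 0), tf)
  expect_error(trim_edges(tf, 19), "half the duration")
})

test_that("SI identities: zero difference, constant offset, uniform null", {
  mk <- function(theta) structure(
    list(theta = theta, times_s = seq_len(ncol(theta)) / 500,
         freqs_hz = seq_len(nrow(theta)), n_trials = 1),
    class = "phase_series")
  set.seed(71)
  th <- matrix(runif(2 * 500, -pi, pi), 2, 500)
  si_same <- sync_index(mk(th), mk(th))
  expect_equal(si_same$si, rep(1 + 0i, 2), ignore_attr = TRUE)
  si_off <- sync_index(mk(rhythmtag:::wrap_angle(th + pi / 3)), mk(th))
  expect_equal(Mod(si_off$si), c(1, 1), tolerance = 1e-12)
  expect_equal(Arg(si_off$si), c(pi / 3, pi / 3), tolerance = 1e-12)
  # independent uniform phases: |SI| <= 3/sqrt(N)
  N <- 1e4
  a <- matrix(runif(N, -pi, pi), 1)
  b <- matrix(runif(N, -pi, pi), 1)
  si_null <- sync_index(mk(a), mk(b))
  expect_lt(Mod(si_null$si), 3 / sqrt(N))
  # mismatched axes rejected
  expect_error(sync_index(mk(th), mk(th[1, , drop = FALSE])), "axes")
})

test_that("SI is invariant to a shared time-varying phase", {
  set.seed(72)
  mk <- function(theta) structure(
    list(theta = theta, times_s = seq_len(ncol(theta)) / 500,
         freqs_hz = 1, n_trials = 1),
    class = "phase_series")
  for (i in 1:5) {
    a <- matrix(runif(300, -pi, pi), 1)
    b <- matrix(runif(300, -pi, pi), 1)
    common <- matrix(cumsum(rnorm(300, sd = 0.3)), 1)
    si0 <- sync_index(mk(a), mk(b))$si
    si1 <- sync_index(mk(rhythmtag:::wrap_angle(a + common)),
                      mk(rhythmtag:::wrap_angle(b + common)))$si
    expect_equal(si1, si0, tolerance = 1e-9)
  }
})

test_that("phase averaging methods agree for unit-normalised coefficients", {
  fs <- 200
  t <- seq(0, 15 - 1 / fs, by = 1 / fs)
  tfs <- lapply(1:3, function(i)
    morlet_tf(cos(2 * pi * 1.5 * t + i) + rnorm(length(t), sd = 0.1),
              fs, c(1.5, 3)))
  p1 <- phase_series(tfs, "coef_average")
  p2 <- phase_series(tfs, "phase_average")
  expect_equal(p1$theta, p2$theta, tolerance = 1e-9)
})

test_that("Rayleigh test matches the closed-form approximation and edge cases", {
  # all angles equal: R = 1, tiny p
  r1 <- rayleigh_test(rep(0.7, 17))
  expect_equal(r1$r, 1)
  n <- 17; R <- 17
  expect_equal(r1$p, exp(sqrt(1 + 4 * n + 4 * (n^2 - R^2)) - (1 + 2 * n)))
  expect_lt(r1$p, 1e-6)
  # evenly spaced angles: R ~ 0, p ~ 1
  r2 <- rayleigh_test(seq(0, 2 * pi, length.out = 13)[-13])
  expect_lt(r2$r, 1e-10)
  expect_gt(r2$p, 0.99)
  expect_error(rayleigh_test(c(0, 1)), "at least 3")
})

test_that("Rayleigh closed form agrees with a brute-force null simulation", {
  set.seed(81)
  n <- 17
  # empirical critical value of the resultant under uniformity
  null_r <- replicate(4000, Mod(mean(exp(1i * runif(n, -pi, pi)))))
  r_crit <- quantile(null_r, 0.95)
  # von Mises kappa = 2 samples: rejection rates by both routes agree
  n_sim <- 400
  rej_p <- 0; rej_r <- 0
  for (i in seq_len(n_sim)) {
    ang <- rhythmtag:::rvonmises(n, 0.4, 2)
    rej_p <- rej_p + (rayleigh_test(ang)$p < 0.05)
    rej_r <- rej_r + (Mod(mean(exp(1i * ang))) > r_crit)
  }
  diff_rate <- abs(rej_p - rej_r) / n_sim
  expect_lt(diff_rate, 0.05)
  expect_gt(rej_p / n_sim, 0.9)  # kappa = 2 with n = 17 is well powered
})

test_that("sync topography masks consistent electrodes and needs n >= 3", {
  # identical participants -> every electrode significant at the common angle
  si <- matrix(complex(modulus = 0.8, argument = 1.1), 17, 6)
  topo <- sync_topography(si)
  expect_true(all(topo$significant))
  expect_equal(topo$mean_angle_rad, rep(1.1, 6))
  expect_equal(topo$mean_strength, rep(0.8, 6))
  expect_error(sync_topography(si[1, , drop = FALSE]), "3 participants")
  # shuffled angles: about 5% of electrodes flagged
  set.seed(91)
  n_el <- 400
  si_null <- matrix(complex(modulus = 0.5,
                            argument = runif(17 * n_el, -pi, pi)), 17, n_el)
  frac <- mean(sync_topography(si_null)$significant)
  expect_lt(frac, 0.05 + 2 * sqrt(0.05 * 0.95 / n_el))
})

test_that("full sync pathway recovers a known lag from envelope-locked trials", {
  fs <- 125
  spec <- duple_triple_rhythm(n_repetitions = 5)
  env <- build_rhythm(spec, fs)
  n <- length(env$samples)
  E <- fft(env$samples)
  k <- round(3 * n / fs)  # beat harmonic bin
  f_harm <- k * fs / n
  phi_env <- Arg(E[k + 1])
  lag <- 0.9
  t <- (seq_len(n) - 1) / fs
  set.seed(101)
  trials <- array(NA_real_, dim = c(8, 2, n))
  for (i in 1:8) for (ch in 1:2)
    trials[i, ch, ] <- cos(2 * pi * f_harm * t + phi_env + lag) +
      pink_noise(n, 1, 2)
  si <- sync_analysis(make_trial_set(trials, fs), env, 3, trim_s = 2)
  expect_true(all(Mod(si) > 0.5))
  expect_equal(Arg(si[1, 1]), lag, tolerance = 10 * pi / 180)
})

test_that("phase recovery is no more precise at slow meter rates than at the beat", {
  # matched in-band SNR (1/f noise) at 0.75 and 3 Hz over fixed-length
  # trials: the slower frequency offers fewer cycles inside the analysis
  # window, so the recovered lag scatters at least as much
  fs <- 125
  spec <- quadruple_rhythm(n_repetitions = 3)
  env <- build_rhythm(spec, fs)
  n <- length(env$samples)
  E <- fft(env$samples)
  t <- (seq_len(n) - 1) / fs
  set.seed(102)
  err_by_f <- sapply(c(0.75, 3), function(f) {
    k <- round(f * n / fs)
    f_harm <- k * fs / n
    phi <- Arg(E[k + 1])
    lag <- 0.7
    errs <- replicate(12, {
      trials <- array(NA_real_, dim = c(10, 1, n))
      for (i in 1:10)
        trials[i, 1, ] <- 0.4 * cos(2 * pi * f_harm * t + phi + lag) +
          pink_noise(n, 1, 3)
      si <- sync_analysis(make_trial_set(trials, fs), env, f, trim_s = 4)
      abs(rhythmtag:::wrap_angle(Arg(si[1, 1]) - lag))
    })
    mean(errs)
  })
  expect_gte(err_by_f[1], err_by_f[2] - 0.02)
})
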