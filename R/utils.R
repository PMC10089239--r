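# Internal numeric helpers shared across modules.

#' @keywords internal
#' @noRd
derive_seed <- function(seed, id = 0L) {
  # deterministic child seed, kept inside 32-bit signed range
  as.integer((as.double(seed) * 48271 + as.double(id) * 110351) %% 2147483629)
}

#' Analytic-signal amplitude via the frequency-domain Hilbert construction.
#' @keywords internal
#' @noRd
analytic_signal <- function(x) {
  n <- length(x)
  if (n == 0L) stop("empty input signal")
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Next highly-composite FFT length >= n (powers of 2 times 3^{0,1}).
#' @keywords internal
#' @noRd
next_fft_len <- function(n) {
  p2 <- 2^ceiling(log2(n))
  cand <- c(p2, 3 * 2^ceiling(log2(n / 3)))
  min(cand[cand >= n])
}

#' Wrap angles into (-pi, pi].
#' @keywords internal
#' @noRd
wrap_angle <- function(theta) {
  out <- (theta + pi) %% (2 * pi) - pi
  out[out == -pi] <- pi
  out
}
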