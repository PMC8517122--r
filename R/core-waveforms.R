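#' Phase-shifted, offset sinusoid
#'
#' The base periodic drive of both waveform models:
#' `sin(2*pi*theta*t - phi) - b`. The offset `b` sets which fraction of the
#' period lies above zero and hence, after squashing, the inspiratory duty
#' fraction (I:E ratio); `b = 0` gives a 1:1 I:E ratio.
#'
#' @param theta Respiratory frequency in breaths/s (> 0).
#' @param phi Phase offset (applied additively inside the sine argument).
#' @param b Vertical offset; values with `|b| < 1` keep the signal
#'   sign-alternating within each period.
#' @param grid A [sample_grid()].
#' @return Numeric vector of length `grid$n`.
#' @examples
#' g <- sample_grid(0.005, 2000)
#' s <- shifted_sine(0.3, 0, 0.7, g)
#' mean(s > 0)  # ~ (pi - 2*asin(0.7)) / (2*pi)
#' @export
shifted_sine <- function(theta, phi, b, grid) {
  assert_that(is.numeric(theta) && length(theta) == 1 && is.finite(theta) &&
                theta > 0, "`theta` must be a single positive number")
  assert_that(is.numeric(phi) && length(phi) == 1 && is.finite(phi),
              "`phi` must be a single finite number")
  assert_that(is.numeric(b) && length(b) == 1 && is.finite(b),
              "`b` must be a single finite number")
  stopifnot(inherits(grid, "sample_grid"))
  sin(2 * pi * theta * grid_times(grid) - phi) - b
}

#' Tanh squashing to a unit-amplitude waveform
#'
#' Elementwise `0.5 * (tanh(a * x) + 1)`: maps any signal into (0, 1). Applied
#' to [shifted_sine()] output it yields a periodic near-rectangular drive with
#' zero base value and unit amplitude; the sharpness `a` controls how abrupt
#' the inspiration/expiration transitions are.
#'
#' @param x Numeric signal.
#' @param a Sharpness (> 0); large values (e.g. 200) give near-binary output.
#' @return Numeric vector, strictly within (0, 1), monotone in `x`.
#' @export
squash <- function(x, a) {
  assert_that(is.numeric(a) && length(a) == 1 && is.finite(a) && a > 0,
              "`a` must be a single positive number")
  assert_that(is.numeric(x) && all(is.finite(x)), "`x` must be a finite numeric signal")
  0.5 * (tanh(a * x) + 1)
}

#' First-order recursive tracking
#'
#' The per-sample recursion
#' `y(i+1) = (1/beta) * drive(i+1) + (1 - 1/beta) * y(i)`, `y(1) = init`.
#' This is a discrete first-order low-pass whose time constant is `beta`
#' samples: it makes the output rise toward (and fall away from) the drive
#' with a gradient controlled by `beta`, which is how the model represents
#' inspiratory and expiratory rates.
#'
#' @param drive Numeric signal.
#' @param beta Smoothing factor (>= 1); `beta = 1` passes the drive through
#'   with a one-step delay from `init`.
#' @param init Initial value `y(1)`.
#' @return Numeric vector the same length as `drive`, bounded by the envelope
#'   of `init` and the drive.
#' @export
first_order_track <- function(drive, beta, init = 0) {
  assert_that(is.numeric(beta) && length(beta) == 1 && is.finite(beta) &&
                beta >= 1, "`beta` must be a single number >= 1")
  assert_that(is.numeric(drive) && length(drive) >= 1 && all(is.finite(drive)),
              "`drive` must be a finite numeric signal")
  assert_that(is.numeric(init) && length(init) == 1 && is.finite(init),
              "`init` must be a single finite number")
  track_rec(drive, beta, init)
}

# Recursion engine (compiled): y[i+1] = x[i+1]/beta + (1-1/beta) y[i]
track_rec <- function(x, beta, init) {
  track_rec_cpp(x, beta, init)
}

#' Leaky differencing
#'
#' The per-sample recursion
#' `y(i+1) = (1/beta) * (y(i) + drive(i+1) - drive(i))`, `y(1) = init`.
#' It responds to transitions of the drive and decays geometrically (ratio
#' `1/beta`) in between, producing spikes at the edges of a rectangular drive
#' — the raw material of the plateau-pressure peaks.
#'
#' @param drive Numeric signal.
#' @param beta Leak factor (>= 1); `beta = 1` telescopes to
#'   `drive - drive[1] + init`.
#' @param init Initial value `y(1)`.
#' @return Numeric vector the same length as `drive`.
#' @export
leaky_diff <- function(drive, beta, init = 0) {
  assert_that(is.numeric(beta) && length(beta) == 1 && is.finite(beta) &&
                beta >= 1, "`beta` must be a single number >= 1")
  assert_that(is.numeric(drive) && length(drive) >= 1 && all(is.finite(drive)),
              "`drive` must be a finite numeric signal")
  assert_that(is.numeric(init) && length(init) == 1 && is.finite(init),
              "`init` must be a single finite number")
  leaky_rec(drive, beta, init)
}

# y[i+1] = (y[i] + dx[i+1]) / beta
leaky_rec <- function(x, beta, init) {
  leaky_rec_cpp(x, beta, init)
}

#' Masked normalization
#'
#' Multiplies a signal elementwise by a mask in \[0, 1\] (typically the
#' rectangular drive or its complement, selecting the inspiratory or
#' expiratory segment) and divides by the maximum of the masked signal, so the
#' result peaks at exactly 1 over the window on which the maximum is taken.
#'
#' @param x Numeric signal.
#' @param mask Numeric signal of the same length with entries in \[0, 1\].
#' @param eps Degeneracy tolerance: if the masked maximum does not exceed
#'   `eps`, normalization is refused.
#' @param what Label naming the term, used in the degeneracy error message.
#' @return `x * mask / max(x * mask)`.
#' @export
mask_normalize <- function(x, mask, eps = 1e-9, what = "signal") {
  assert_that(is.numeric(x) && is.numeric(mask) && length(x) == length(mask),
              "`x` and `mask` must be numeric signals of equal length")
  assert_that(all(is.finite(mask)) && all(mask >= 0) && all(mask <= 1),
              "`mask` entries must lie in [0, 1]")
  xm <- x * mask
  m <- max(xm)
  if (!is.finite(m) || m <= eps) {
    stop_dilvr(sprintf(
      "degenerate normalization of %s: masked maximum %.3g <= eps = %.3g",
      what, m, eps), "dilvr_degenerate_normalization")
  }
  xm / m
}
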