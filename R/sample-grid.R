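#' Uniform sample grid
#'
#' All simulated signals live on a uniform time discretization. The grid also
#' carries the number of warm-up (burn-in) periods that are simulated before
#' the analysis window and discarded, so that the recursive model terms are in
#' periodic steady state before masking and normalization.
#'
#' @param dt Seconds per sample (> 0).
#' @param n Number of samples (positive integer).
#' @param t_start Time of the first sample in seconds.
#' @param burn_in_periods Nonnegative number of warm-up periods simulated and
#'   discarded before the analysis window.
#' @return An object of class `sample_grid`.
#' @examples
#' g <- sample_grid(dt = 0.005, n = 667)
#' range(grid_times(g))
#' @export
sample_grid <- function(dt, n, t_start = 0, burn_in_periods = 3) {
  assert_that(is.numeric(dt) && length(dt) == 1 && is.finite(dt) && dt > 0,
              "`dt` must be a single positive number")
  assert_that(is.numeric(n) && length(n) == 1 && is.finite(n) && n >= 1 &&
                n == round(n),
              "`n` must be a positive integer")
  assert_that(is.numeric(t_start) && length(t_start) == 1 && is.finite(t_start),
              "`t_start` must be a single finite number")
  assert_that(is.numeric(burn_in_periods) && length(burn_in_periods) == 1 &&
                is.finite(burn_in_periods) && burn_in_periods >= 0,
              "`burn_in_periods` must be a nonnegative number")
  structure(
    list(dt = dt, n = as.integer(n), t_start = t_start,
         burn_in_periods = burn_in_periods),
    class = "sample_grid"
  )
}

#' Sample times of a grid
#'
#' @param grid A [sample_grid()].
#' @return Numeric vector of length `grid$n`: `t_start + (0:(n-1)) * dt`.
#' @export
grid_times <- function(grid) {
  stopifnot(inherits(grid, "sample_grid"))
  grid$t_start + (seq_len(grid$n) - 1) * grid$dt
}

#' @export
print.sample_grid <- function(x, ...) {
  cat(sprintf("<sample_grid> n = %d, dt = %g s (%.4g s total), t_start = %g, burn-in = %g periods\n",
              x$n, x$dt, x$n * x$dt, x$t_start, x$burn_in_periods))
  invisible(x)
}

# Grid covering one full breath period at a given rate.
period_grid <- function(theta, dt = 0.005, burn_in_periods = 3, t_start = 0) {
  sample_grid(dt = dt, n = ceiling(1 / (theta * dt)), t_start = t_start,
              burn_in_periods = burn_in_periods)
}

check_covers_period <- function(grid, theta) {
  if (grid$n * grid$dt < 1 / theta - 1e-12) {
    stop_dilvr(sprintf(
      "grid covers %.4g s but one breath period is %.4g s; simulation window must span at least one period",
      grid$n * grid$dt, 1 / theta), "dilvr_invalid_parameter")
  }
  invisible(TRUE)
}

#' One breath's sampled traces
#'
#' Container for a single breath: airway pressure (cmH2O), volume (ml) and
#' optionally flow (ml/s) on a shared [sample_grid()].
#'
#' @param grid A [sample_grid()].
#' @param pressure Numeric vector of airway pressure in cmH2O, length `grid$n`.
#' @param volume Numeric vector of volume in ml, length `grid$n`.
#' @param flow Optional numeric vector of flow in ml/s, length `grid$n`. When
#'   `NULL` it can be derived later by finite differences of volume.
#' @param meta Free-form list of provenance labels (regime, ground truth, ...).
#' @return An object of class `breath_record`.
#' @export
breath_record <- function(grid, pressure, volume, flow = NULL, meta = list()) {
  stopifnot(inherits(grid, "sample_grid"))
  check_trace <- function(x, nm) {
    assert_that(is.numeric(x) && length(x) == grid$n,
                sprintf("`%s` must be numeric of length grid$n = %d", nm, grid$n))
    assert_that(all(is.finite(x)), sprintf("`%s` must contain only finite values", nm))
  }
  check_trace(pressure, "pressure")
  check_trace(volume, "volume")
  if (!is.null(flow)) check_trace(flow, "flow")
  structure(
    list(grid = grid, pressure = as.numeric(pressure),
         volume = as.numeric(volume),
         flow = if (is.null(flow)) NULL else as.numeric(flow),
         meta = meta),
    class = "breath_record"
  )
}

#' @export
print.breath_record <- function(x, ...) {
  cat(sprintf("<breath_record> %d samples at dt = %g s (%.3g s)\n",
              x$grid$n, x$grid$dt, x$grid$n * x$grid$dt))
  cat(sprintf("  pressure: [%.3g, %.3g] cmH2O;  volume: [%.3g, %.3g] ml%s\n",
              min(x$pressure), max(x$pressure), min(x$volume), max(x$volume),
              if (is.null(x$flow)) "" else ";  flow present"))
  if (length(x$meta)) {
    keys <- names(x$meta)
    cat("  meta:", paste(keys, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
plot.breath_record <- function(x, ...) {
  t <- grid_times(x$grid)
  op <- par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(par(op))
  plot(t, x$volume, type = "l", xlab = "time (s)", ylab = "volume (ml)", ...)
  plot(t, x$pressure, type = "l", xlab = "time (s)", ylab = "pressure (cmH2O)", ...)
  invisible(x)
}

# Flow by central finite differences (one-sided at the endpoints).
derive_flow <- function(volume, dt) {
  n <- length(volume)
  if (n < 3) stop_dilvr("need at least 3 samples to derive flow", "dilvr_invalid_parameter")
  f <- numeric(n)
  f[2:(n - 1)] <- (volume[3:n] - volume[1:(n - 2)]) / (2 * dt)
  f[1] <- (volume[2] - volume[1]) / dt
  f[n] <- (volume[n] - volume[n - 1]) / dt
  f
}

# Ensure a breath record carries a flow trace.
ensure_flow <- function(breath) {
  if (is.null(breath$flow)) breath$flow <- derive_flow(breath$volume, breath$grid$dt)
  breath
}
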