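# Shared fixtures: grids and parameter sets used across test files.

# dense grid spanning `periods` breath periods at rate theta
grid_for <- function(theta, periods = 3, dt = 0.005, burn_in = 3) {
  sample_grid(dt, ceiling(periods / (theta * dt)), burn_in_periods = burn_in)
}

# analytic duty fraction of the thresholded sinusoid: fraction of the period
# with sin(.) > b
duty_fraction <- function(b) (pi - 2 * asin(b)) / (2 * pi)

# time for a rising trace to first reach `frac` of its maximum
rise_time_to <- function(x, dt, frac = 0.95) {
  dt * (which(x >= frac * max(x))[1] - 1)
}

# count local maxima above a level
count_peaks_above <- function(x, level) {
  n <- length(x)
  sum(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] > x[3:n] & x[2:(n - 1)] > level)
}

# small multi-start spec centered at a preset's generating values
spec_at_truth <- function(preset, n_starts = 10, seed = 7, halfwidth = 0.3, ...) {
  fit_spec(preset$volume, preset$pressure, n_starts = n_starts, seed = seed,
           halfwidth = halfwidth, ...)
}
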