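#' Volume-model parameters
#'
#' The volume waveform is built from a rectangular drive (squashed sinusoid)
#' whose rising and falling flanks are tracked by two first-order recursions;
#' the two masked, normalized tracks are summed and scaled. Beyond the shared
#' respiratory frequency `theta`, the model has six parameters.
#'
#' @param theta Respiratory frequency, breaths/s (> 0). Shared with the
#'   pressure model of the same breath.
#' @param a1 Sharpness of the rectangular drive (> 0); higher is sharper.
#' @param b1 Duty offset controlling the I:E ratio (`|b1| < 1`); higher values
#'   shorten inspiration; `b1 = 0` gives 1:1.
#' @param phi1 Phase: where in the respiratory cycle the record starts.
#' @param beta1 Inspiratory smoothing (>= 1, samples); higher values slow the
#'   rising signal (lower compliance and/or higher resistance in PCV).
#' @param beta2 Expiratory smoothing (>= 1, samples); higher values slow the
#'   falling signal (longer expiratory time constant).
#' @param Av Peak amplitude in ml (tidal volume scale).
#' @return An object of class `volume_params` (named list).
#' @export
volume_params <- function(theta = 0.3, a1 = 200, b1 = 0.7, phi1 = 0,
                          beta1 = 30, beta2 = 10, Av = 1) {
  p <- list(theta = theta, a1 = a1, b1 = b1, phi1 = phi1,
            beta1 = beta1, beta2 = beta2, Av = Av)
  for (nm in names(p)) {
    assert_that(is.numeric(p[[nm]]) && length(p[[nm]]) == 1 && is.finite(p[[nm]]),
                sprintf("`%s` must be a single finite number", nm))
  }
  assert_that(theta > 0, "`theta` must be > 0")
  assert_that(a1 > 0, "`a1` must be > 0")
  assert_that(abs(b1) < 1, "`b1` must satisfy |b1| < 1 (otherwise the drive saturates)")
  assert_that(beta1 >= 1, "`beta1` must be >= 1")
  assert_that(beta2 >= 1, "`beta2` must be >= 1")
  structure(p, class = "volume_params")
}

#' Pressure-model parameters
#'
#' The pressure waveform is composed of three normalized components plus a
#' baseline: the main rise/fall component (amplitude `Ap1`, the plateau
#' pressure above PEEP), the plateau-peak component produced by leaky
#' differencing of the drive (amplitude `Ap2`; peaks at the start and end of
#' the plateau, associated with ventilator dyssynchrony), and the low-volume
#' knee component produced by a short sinusoidal pulse (amplitude `Ap3`).
#' Beyond the shared `theta`, the model has fourteen parameters.
#'
#' @param theta Respiratory frequency, breaths/s; must equal the paired
#'   volume model's `theta` in a combined breath.
#' @param a2,b2,phi2 Sharpness, duty offset (`|b2| < 1`) and phase of the main
#'   rectangular drive.
#' @param a3,b3,phi3 Sharpness, offset and phase of the short pulse shaping
#'   the initial low-volume rise (higher `a3`, `b3`: slower rise, higher
#'   low-volume compliance).
#' @param beta3 Inspiratory pressure rise smoothing (>= 1); higher is slower
#'   (higher high-volume compliance in VCV).
#' @param beta4 Expiratory pressure fall smoothing (>= 1).
#' @param beta5,beta6 Plateau-peak shape factors (>= 1); values near 1 give
#'   broad peaks, larger values sharper ones.
#' @param Ap1 Plateau amplitude above baseline, cmH2O.
#' @param Ap2 Plateau-peak amplitude, cmH2O (>= 0; 0 switches the feature off).
#' @param Ap3 Low-volume-knee amplitude, cmH2O (>= 0; 0 switches it off).
#' @param Ap4 Baseline pressure (PEEP), cmH2O.
#' @return An object of class `pressure_params` (named list).
#' @export
pressure_params <- function(theta = 0.3, a2 = 200, b2 = 0.7, phi2 = 0,
                            a3 = 10, b3 = 0.9, phi3 = -0.6,
                            beta3 = 5, beta4 = 5, beta5 = 1.001, beta6 = 1.1111,
                            Ap1 = 1, Ap2 = 0.5, Ap3 = 0.5, Ap4 = 0) {
  p <- list(theta = theta, a2 = a2, b2 = b2, phi2 = phi2,
            a3 = a3, b3 = b3, phi3 = phi3,
            beta3 = beta3, beta4 = beta4, beta5 = beta5, beta6 = beta6,
            Ap1 = Ap1, Ap2 = Ap2, Ap3 = Ap3, Ap4 = Ap4)
  for (nm in names(p)) {
    assert_that(is.numeric(p[[nm]]) && length(p[[nm]]) == 1 && is.finite(p[[nm]]),
                sprintf("`%s` must be a single finite number", nm))
  }
  assert_that(theta > 0, "`theta` must be > 0")
  assert_that(a2 > 0, "`a2` must be > 0")
  assert_that(a3 > 0, "`a3` must be > 0")
  assert_that(abs(b2) < 1, "`b2` must satisfy |b2| < 1 (otherwise the drive saturates)")
  for (nm in c("beta3", "beta4", "beta5", "beta6")) {
    assert_that(p[[nm]] >= 1, sprintf("`%s` must be >= 1", nm))
  }
  assert_that(Ap2 >= 0, "`Ap2` must be >= 0")
  assert_that(Ap3 >= 0, "`Ap3` must be >= 0")
  structure(p, class = "pressure_params")
}

#' @export
print.volume_params <- function(x, ...) {
  cat("<volume_params>\n")
  print(unlist(x))
  invisible(x)
}

#' @export
print.pressure_params <- function(x, ...) {
  cat("<pressure_params>\n")
  print(unlist(x))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Internal simulation cores. These accept a plain named list/vector and skip
# S3 validation: they sit inside the multi-start objective hot loop.
#
# Burn-in: recursions start at 0 and are run over `burn_in_periods` warm-up
# periods (extended automatically to at least 5 * max(beta) samples so that
# slow recursions also reach periodic steady state); the warm-up samples are
# discarded before masking and normalization. The normalization window is the
# analysis window extended, if necessary, to cover one full period, so the
# masked maxima always see a complete breath.
# ---------------------------------------------------------------------------

# Model-composition normalization: multiply by the segment mask, divide by
# the maximum of the raw recursion vector over the window. The raw-vector
# denominator (rather than the masked maximum) is what makes the summed
# inspiratory + expiratory components peak at the amplitude parameter rather
# than overshooting it where the two masked segments overlap.
raw_max_normalize <- function(x, mask, what) {
  m <- max(x)
  if (!is.finite(m) || m <= 1e-9) {
    stop_dilvr(sprintf("degenerate normalization of %s: maximum %.3g ~ 0", what, m),
               "dilvr_degenerate_normalization")
  }
  x * mask / m
}

# Warm-up long enough for every recursion to reach periodic steady state:
# at least `burn_in_periods` periods, extended to 8 time constants of the
# slowest recursion. For first-order tracking the time constant is ~beta
# samples; for leaky differencing the decay ratio is 1/beta, so the time
# constant is 1/log(beta) samples (capped: beta ~ 1 decays arbitrarily slowly).
tau_leak <- function(beta) {
  if (beta <= 1 + 1e-9) 0 else min(1 / log(beta), 2500)
}

extend_window <- function(grid, theta, tau_max) {
  period_samples <- 1 / (theta * grid$dt)
  n_burn <- max(ceiling(grid$burn_in_periods * period_samples),
                ceiling(8 * tau_max))
  n_win <- max(grid$n, ceiling(period_samples))
  t <- grid$t_start + ((-n_burn):(n_win - 1)) * grid$dt
  list(t = t, post = (n_burn + 1):(n_burn + n_win))
}

sim_volume_core <- function(p, grid, masks = "corrected", components = FALSE) {
  if (!components) {
    v <- sim_volume_cpp(p$theta, p$a1, p$b1, p$phi1, p$beta1, p$beta2, p$Av,
                        grid$dt, grid$n, grid$t_start, grid$burn_in_periods,
                        !identical(masks, "as-printed"))
    if (!length(v)) {
      stop_dilvr("degenerate normalization in volume-model simulation (a tracking term has maximum ~ 0)",
                 "dilvr_degenerate_normalization")
    }
    return(v)
  }
  ext <- extend_window(grid, p$theta, max(p$beta1, p$beta2))
  fs1 <- sin(2 * pi * p$theta * ext$t - p$phi1) - p$b1
  fb1 <- 0.5 * (tanh(p$a1 * fs1) + 1)
  fv1 <- track_rec(fb1, p$beta1, 0)
  fv2 <- track_rec(fb1, p$beta2, 0)
  w <- ext$post
  fb1 <- fb1[w]; fv1 <- fv1[w]; fv2 <- fv2[w]
  mask2 <- if (identical(masks, "as-printed")) fb1 else 1 - fb1
  fv1n <- raw_max_normalize(fv1, fb1, "fv1 (inspiratory volume term)")
  fv2n <- raw_max_normalize(fv2, mask2, "fv2 (expiratory volume term)")
  V <- p$Av * (fv1n + fv2n)
  keep <- seq_len(grid$n)
  if (!components) return(V[keep])
  list(V = V[keep], fb1 = fb1[keep], fv1 = fv1n[keep], fv2 = fv2n[keep])
}

sim_pressure_core <- function(p, grid, masks = "corrected", components = FALSE) {
  if (!components) {
    v <- sim_pressure_cpp(p$theta, p$a2, p$b2, p$phi2, p$a3, p$b3, p$phi3,
                          p$beta3, p$beta4, p$beta5, p$beta6,
                          p$Ap1, p$Ap2, p$Ap3, p$Ap4,
                          grid$dt, grid$n, grid$t_start, grid$burn_in_periods,
                          !identical(masks, "as-printed"))
    if (!length(v)) {
      stop_dilvr("degenerate normalization in pressure-model simulation (a component term has maximum ~ 0)",
                 "dilvr_degenerate_normalization")
    }
    return(v)
  }
  tau <- max(p$beta3, p$beta4,
             if (p$Ap2 > 0) c(tau_leak(p$beta5), tau_leak(p$beta6)) else 0)
  ext <- extend_window(grid, p$theta, tau)
  fs2 <- sin(2 * pi * p$theta * ext$t - p$phi2) - p$b2
  fb2 <- 0.5 * (tanh(p$a2 * fs2) + 1)
  fp11 <- track_rec(fb2, p$beta3, 0)
  fp12 <- track_rec(fb2, p$beta4, 0)
  if (p$Ap2 > 0) {
    fp21 <- leaky_rec(fb2, p$beta5, 0)
    fp22 <- fp21 * fb2
    fp23 <- abs(leaky_rec(fp22, p$beta6, 0))
  }
  w <- ext$post
  fb2 <- fb2[w]; fp11 <- fp11[w]; fp12 <- fp12[w]
  mask12 <- if (identical(masks, "as-printed")) fb2 else 1 - fb2
  fp11n <- raw_max_normalize(fp11, fb2, "fp11 (inspiratory pressure term)")
  fp12n <- raw_max_normalize(fp12, mask12, "fp12 (expiratory pressure term)")
  fp13 <- p$Ap1 * (fp11n + fp12n)
  nw <- length(w)
  if (p$Ap2 > 0) {
    fp23 <- fp23[w]
    m23 <- max(fp23)
    if (m23 <= 1e-9) {
      stop_dilvr("degenerate normalization of fp23 (plateau-peak term): maximum ~ 0",
                 "dilvr_degenerate_normalization")
    }
    fp24 <- p$Ap2 * fp23 / m23
  } else {
    fp24 <- numeric(nw)
  }
  if (p$Ap3 > 0) {
    fp31 <- sin(2 * pi * p$theta * ext$t[w] - p$phi3) - p$b3
    fp32 <- 0.5 * (tanh(p$a3 * fp31) + 1)
    g <- fp32 * (1 - (fp11n + fp12n))
    mg <- max(g)
    if (mg <= 1e-9) {
      stop_dilvr("degenerate normalization of fp33 (low-volume knee term): pulse does not overlap the low-pressure window",
                 "dilvr_degenerate_normalization")
    }
    fp33 <- p$Ap3 * g / mg
  } else {
    fp33 <- numeric(nw)
  }
  P <- fp13 + fp24 + fp33 + p$Ap4
  keep <- seq_len(grid$n)
  if (!components) return(P[keep])
  list(P = P[keep], fb2 = fb2[keep], fp11 = fp11n[keep], fp12 = fp12n[keep],
       fp13 = fp13[keep], fp24 = fp24[keep], fp33 = fp33[keep])
}

#' Simulate the volume waveform
#'
#' @param p A [volume_params()] object.
#' @param grid A [sample_grid()]; must cover at least one breath period
#'   `1/theta`.
#' @param masks `"corrected"` (default) masks the expiratory tracking term by
#'   the complement of the rectangular drive, so `beta2` controls the falling
#'   gradient; `"as-printed"` applies the inspiratory drive as the mask to
#'   both terms, reproducing the construction formulas literally.
#' @param components If `TRUE`, also return the constitutive terms
#'   (`fb1`, `fv1`, `fv2`).
#' @return Numeric volume trace in ml (or a list of components).
#' @examples
#' g <- sample_grid(0.005, 667)
#' V <- simulate_volume(volume_params(), g)
#' max(V)  # = Av = 1
#' @export
simulate_volume <- function(p, grid, masks = c("corrected", "as-printed"),
                            components = FALSE) {
  stopifnot(inherits(p, "volume_params"), inherits(grid, "sample_grid"))
  masks <- match.arg(masks)
  check_covers_period(grid, p$theta)
  sim_volume_core(p, grid, masks = masks, components = components)
}

#' Simulate the pressure waveform
#'
#' @param p A [pressure_params()] object.
#' @inheritParams simulate_volume
#' @param components If `TRUE`, also return the constitutive terms
#'   (`fb2`, `fp11`, `fp12`, `fp13`, `fp24`, `fp33`).
#' @return Numeric pressure trace in cmH2O (or a list of components).
#' @export
simulate_pressure <- function(p, grid, masks = c("corrected", "as-printed"),
                              components = FALSE) {
  stopifnot(inherits(p, "pressure_params"), inherits(grid, "sample_grid"))
  masks <- match.arg(masks)
  check_covers_period(grid, p$theta)
  sim_pressure_core(p, grid, masks = masks, components = components)
}

#' Simulate a combined breath
#'
#' Simulates the volume and pressure models on a shared grid. The two models
#' are deliberately not mechanically coupled; they share only the respiratory
#' frequency `theta`, which is enforced here. Flow is computed as the central
#' finite difference of volume.
#'
#' @param vp A [volume_params()] object.
#' @param pp A [pressure_params()] object with the same `theta`.
#' @param grid A [sample_grid()].
#' @param masks See [simulate_volume()].
#' @param meta Optional provenance list stored on the record.
#' @return A [breath_record()].
#' @export
simulate_breath <- function(vp, pp, grid, masks = c("corrected", "as-printed"),
                            meta = list()) {
  stopifnot(inherits(vp, "volume_params"), inherits(pp, "pressure_params"))
  masks <- match.arg(masks)
  if (!isTRUE(all.equal(vp$theta, pp$theta, tolerance = 1e-12))) {
    stop_dilvr(sprintf(
      "volume and pressure models must share the respiratory frequency: theta = %g vs %g",
      vp$theta, pp$theta), "dilvr_coupling_error")
  }
  V <- simulate_volume(vp, grid, masks = masks)
  P <- simulate_pressure(pp, grid, masks = masks)
  breath_record(grid, pressure = P, volume = V,
                flow = derive_flow(V, grid$dt), meta = meta)
}

#' Model-derived lung compliance
#'
#' The ratio of the volume-model amplitude to the plateau-pressure amplitude,
#' `Cd = Av / Ap1` (ml/cmH2O) — the model analogue of tidal volume over
#' driving pressure. It decreases with lung injury and tracks the compliance
#' estimated by the single-compartment model.
#'
#' @param Av Volume amplitude, ml.
#' @param Ap1 Plateau-pressure amplitude, cmH2O (non-zero).
#' @return An object of class `compliance_report` with fields `Cd`, `Av`,
#'   `Ap1`.
#' @examples
#' dilv_compliance(1.03, 35.53)$Cd  # ~ 0.029 ml/cmH2O
#' @export
dilv_compliance <- function(Av, Ap1) {
  assert_that(is.numeric(Av) && length(Av) == 1 && is.finite(Av),
              "`Av` must be a single finite number")
  assert_that(is.numeric(Ap1) && length(Ap1) == 1 && is.finite(Ap1),
              "`Ap1` must be a single finite number")
  if (Ap1 == 0) {
    stop_dilvr("`Ap1` must be non-zero to define compliance Cd = Av/Ap1",
               "dilvr_invalid_parameter")
  }
  structure(list(Cd = Av / Ap1, Av = Av, Ap1 = Ap1), class = "compliance_report")
}

#' @export
print.compliance_report <- function(x, ...) {
  cat(sprintf("Model-derived compliance Cd = Av/Ap1 = %.4g / %.4g = %.4g ml/cmH2O\n",
              x$Av, x$Ap1, x$Cd))
  invisible(x)
}

#' Parameter registry
#'
#' One row per model parameter: which sub-model it belongs to (the
#' respiratory frequency `theta` is shared), what it controls, its default
#' hard bounds used by [fit_spec()], and whether it is estimated by default
#' or kept frozen at its configured value.
#'
#' @return A data frame with columns `name`, `model`, `role`, `lower`,
#'   `upper`, `free_default`.
#' @examples
#' table(dilv_parameters()$model)
#' @export
dilv_parameters <- function() {
  reg <- rbind(
    data.frame(name = "theta", model = "shared",
               role = "respiratory frequency (breaths/s)",
               lower = 0.01, upper = 10, free_default = TRUE),
    data.frame(
      name = c("a1", "b1", "phi1", "beta1", "beta2", "Av"),
      model = "volume",
      role = c("drive sharpness", "duty offset (I:E ratio)", "phase",
               "inspiratory smoothing", "expiratory smoothing",
               "amplitude (ml)"),
      lower = c(0.1, -0.99, -2 * pi, 1, 1, 0),
      upper = c(1000, 0.99, 2 * pi, 5000, 5000, 1e5),
      free_default = c(FALSE, TRUE, TRUE, TRUE, TRUE, TRUE)),
    data.frame(
      name = c("a2", "b2", "phi2", "a3", "b3", "phi3", "beta3", "beta4",
               "beta5", "beta6", "Ap1", "Ap2", "Ap3", "Ap4"),
      model = "pressure",
      role = c("drive sharpness", "duty offset (I:E ratio)", "phase",
               "low-volume pulse sharpness", "low-volume pulse offset",
               "low-volume pulse phase", "inspiratory rise smoothing",
               "expiratory fall smoothing", "plateau-peak shape",
               "plateau-peak sharpness", "plateau amplitude (cmH2O)",
               "plateau-peak amplitude (cmH2O)",
               "low-volume knee amplitude (cmH2O)", "baseline / PEEP (cmH2O)"),
      lower = c(0.1, -0.99, -2 * pi, 0.1, -2, -2 * pi, 1, 1, 1, 1, 0, 0, 0, -100),
      upper = c(1000, 0.99, 2 * pi, 1000, 2, 2 * pi, 5000, 5000, 100, 100,
                1e4, 1e4, 1e4, 100),
      free_default = c(FALSE, TRUE, TRUE, FALSE, FALSE, FALSE, TRUE, TRUE,
                       FALSE, FALSE, TRUE, FALSE, FALSE, TRUE))
  )
  rownames(reg) <- NULL
  reg
}

#' Bundled reference parameter sets
#'
#' Named parameter presets used throughout the package as generating
#' conditions for synthetic data and as worked-example inputs. They are
#' reference estimates for: a healthy and an injured adult mouse under
#' pressure-controlled ventilation, and an ICU patient (no dyssynchrony) at
#' the beginning and end of a monitored breath sequence with plateau-peak
#' features present. The mouse presets have the plateau-peak feature switched
#' off (`Ap2 = 0`).
#'
#' @param which Optional preset name; omit to get the full named list.
#' @return A list with elements `volume` ([volume_params()]), `pressure`
#'   ([pressure_params()]) and `label`, or a named list of such presets.
#' @examples
#' names(dilv_presets())
#' dilv_presets("healthy_mouse")$volume$Av
#' @export
dilv_presets <- function(which = NULL) {
  presets <- list(
    healthy_mouse = list(
      label = "healthy mouse, PCV",
      volume = volume_params(theta = 0.66, a1 = 9.67, b1 = 0.59, phi1 = 0.09,
                             beta1 = 112.97, beta2 = 28.35, Av = 1.03),
      pressure = pressure_params(theta = 0.66, a2 = 52.06, b2 = 0.80,
                                 phi2 = 0.34, a3 = 2.55, b3 = 1.00, phi3 = 0,
                                 beta3 = 50.00, beta4 = 18.54,
                                 beta5 = 1.001, beta6 = 1.1111,
                                 Ap1 = 35.53, Ap2 = 0, Ap3 = 14.00, Ap4 = 0.06)),
    injured_mouse = list(
      label = "lavage-injured mouse, PCV",
      volume = volume_params(theta = 0.66, a1 = 15.41, b1 = 0.53, phi1 = -0.01,
                             beta1 = 458.95, beta2 = 10.60, Av = 0.70),
      pressure = pressure_params(theta = 0.66, a2 = 32.11, b2 = 0.66,
                                 phi2 = 0.09, a3 = 5.11, b3 = 0.53, phi3 = 0,
                                 beta3 = 100.84, beta4 = 11.93,
                                 beta5 = 1.001, beta6 = 1.1111,
                                 Ap1 = 35.02, Ap2 = 0, Ap3 = 9.60, Ap4 = 0)),
    human1_begin = list(
      label = "ICU patient 1, sequence beginning (PEEP 20)",
      volume = volume_params(theta = 0.34, a1 = 7.51, b1 = 0.66, phi1 = 0.42,
                             beta1 = 10.96, beta2 = 12.42, Av = 402.61),
      pressure = pressure_params(theta = 0.34, a2 = 27.39, b2 = 0.67,
                                 phi2 = 0.35, a3 = 7.71, b3 = 0.91, phi3 = 0.15,
                                 beta3 = 7.25, beta4 = 1.95,
                                 beta5 = 1.0014, beta6 = 1.1262,
                                 Ap1 = 16.58, Ap2 = 3.80, Ap3 = 3.90,
                                 Ap4 = 19.98)),
    human1_end = list(
      label = "ICU patient 1, sequence ending (PEEP 18)",
      volume = volume_params(theta = 0.35, a1 = 7.57, b1 = 0.63, phi1 = 0.51,
                             beta1 = 12.53, beta2 = 12.64, Av = 337.08),
      pressure = pressure_params(theta = 0.35, a2 = 17.73, b2 = 0.66,
                                 phi2 = 0.32, a3 = 18.37, b3 = 0.90, phi3 = 0.14,
                                 beta3 = 12.88, beta4 = 2.52,
                                 beta5 = 1.0048, beta6 = 1.0771,
                                 Ap1 = 11.64, Ap2 = 2.48, Ap3 = 4.10,
                                 Ap4 = 17.91))
  )
  if (is.null(which)) return(presets)
  assert_that(which %in% names(presets),
              sprintf("unknown preset '%s'; available: %s", which,
                      paste(names(presets), collapse = ", ")))
  presets[[which]]
}
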