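VOL_PARS <- c("theta", "a1", "b1", "phi1", "beta1", "beta2", "Av")
PRES_PARS <- c("theta", "a2", "b2", "phi2", "a3", "b3", "phi3",
               "beta3", "beta4", "beta5", "beta6", "Ap1", "Ap2", "Ap3", "Ap4")
PENALTY_MSE <- 1e12

default_free <- function(model) {
  reg <- dilv_parameters()
  keep <- reg$free_default & (reg$model %in% c(model, "shared"))
  reg$name[keep]
}

#' Estimation configuration
#'
#' Describes one breath-by-breath estimation run: which parameters are free,
#' their hard bounds, where the multi-start initializations are sampled from,
#' how many starts to run, and how the shared respiratory frequency `theta`
#' is treated. Parameters not listed as free are frozen at the values given
#' by `volume` / `pressure` and returned unchanged.
#'
#' Initializations are drawn uniformly from
#' `center +/- halfwidth * |center|` (intersected with the bounds), one
#' independent deterministic stream per sub-model, so results are exactly
#' reproducible for a given seed and the first `k` starts of a longer run
#' coincide with a shorter run's starts.
#'
#' @param volume A [volume_params()] object: initialization centers and
#'   frozen values for the volume model.
#' @param pressure A [pressure_params()] object: same for the pressure model.
#' @param free Named list with character vectors `volume` and `pressure`
#'   selecting the free parameters. Defaults to the registry's default free
#'   set (`dilv_parameters()$free_default`): drive sharpness, the low-volume
#'   pulse shape and the plateau-peak group are frozen unless requested.
#' @param bounds Optional named list of `c(lo, hi)` pairs overriding the
#'   registry's hard bounds for individual parameters.
#' @param halfwidth Fraction of `|center|` used as the initialization
#'   half-interval (default 0.3), or a named numeric vector of absolute
#'   half-widths per parameter.
#' @param n_starts Number of optimization starts per sub-model (default 100).
#' @param seed Integer seed controlling all initialization draws.
#' @param theta_mode `"from_volume"` (default): `theta` is estimated within
#'   the volume fit and then frozen for the pressure fit; `"fixed"`: frozen
#'   at its center in both; `"joint"`: a single optimization of the union of
#'   free parameters minimizing the sum of both MSEs.
#' @param dt Sampling step (s) on which fitting is performed; breaths at a
#'   different step are resampled first. The smoothing parameters `beta*` are
#'   per-sample quantities, so `dt` is part of the configuration and fitted
#'   values are comparable only at equal `dt`.
#' @param masks Mask convention passed to the simulators, see
#'   [simulate_volume()].
#' @param control List of optimizer settings: `maxit` (default 500), `factr`
#'   (objective tolerance factor for `optim`'s L-BFGS-B, default 1e7) and
#'   `polish_maxit` (iteration budget of the derivative-free simplex polish
#'   applied after each gradient-based start, default 300; 0 disables).
#' @return An object of class `fit_spec`.
#' @export
fit_spec <- function(volume, pressure, free = NULL, bounds = NULL,
                     halfwidth = 0.3, n_starts = 100, seed = 1,
                     theta_mode = c("from_volume", "fixed", "joint"),
                     dt = 0.005, masks = c("corrected", "as-printed"),
                     control = list()) {
  stopifnot(inherits(volume, "volume_params"), inherits(pressure, "pressure_params"))
  theta_mode <- match.arg(theta_mode)
  masks <- match.arg(masks)
  assert_that(is.numeric(n_starts) && length(n_starts) == 1 && n_starts >= 1,
              "`n_starts` must be a positive integer")
  assert_that(is.numeric(seed) && length(seed) == 1 && is.finite(seed),
              "`seed` must be a single integer")
  assert_that(is.numeric(dt) && length(dt) == 1 && dt > 0,
              "`dt` must be a single positive number")
  if (is.null(free)) {
    free <- list(volume = default_free("volume"), pressure = default_free("pressure"))
  }
  assert_that(is.list(free) && all(c("volume", "pressure") %in% names(free)),
              "`free` must be a list with elements `volume` and `pressure`")
  assert_that(all(free$volume %in% VOL_PARS),
              sprintf("unknown volume parameters in `free`: %s",
                      paste(setdiff(free$volume, VOL_PARS), collapse = ", ")))
  assert_that(all(free$pressure %in% PRES_PARS),
              sprintf("unknown pressure parameters in `free`: %s",
                      paste(setdiff(free$pressure, PRES_PARS), collapse = ", ")))

  reg <- dilv_parameters()
  bnd <- matrix(c(reg$lower, reg$upper), ncol = 2,
                dimnames = list(reg$name, c("lower", "upper")))
  if (!is.null(bounds)) {
    assert_that(is.list(bounds) && all(names(bounds) %in% reg$name),
                "`bounds` must be a named list over registry parameter names")
    for (nm in names(bounds)) {
      b <- bounds[[nm]]
      assert_that(is.numeric(b) && length(b) == 2 && all(is.finite(b)) && b[1] < b[2],
                  sprintf("`bounds$%s` must be a finite pair lo < hi", nm))
      bnd[nm, ] <- b
    }
  }
  if (theta_mode == "from_volume" && !("theta" %in% free$volume)) {
    free$volume <- c("theta", free$volume)
  }
  if (theta_mode %in% c("from_volume", "fixed")) {
    free$pressure <- setdiff(free$pressure, "theta")
  }
  if (theta_mode == "fixed") free$volume <- setdiff(free$volume, "theta")

  ctl <- modifyList(list(maxit = 500, factr = 1e7, polish_maxit = 300), control)
  structure(
    list(volume = volume, pressure = pressure, free = free, bounds = bnd,
         halfwidth = halfwidth, n_starts = as.integer(n_starts),
         seed = as.integer(seed), theta_mode = theta_mode, dt = dt,
         masks = masks, control = ctl),
    class = "fit_spec")
}

#' @export
print.fit_spec <- function(x, ...) {
  cat(sprintf("<fit_spec> %d starts, seed %d, theta_mode = %s, dt = %g s\n",
              x$n_starts, x$seed, x$theta_mode, x$dt))
  cat("  free (volume):  ", paste(x$free$volume, collapse = ", "), "\n")
  cat("  free (pressure):", paste(x$free$pressure, collapse = ", "), "\n")
  invisible(x)
}

# mse between a simulated trace at `full` params and the measured trace;
# degenerate simulations return a large penalty so multi-start continues.
mse_for <- function(full, breath, which, masks) {
  sim <- tryCatch(
    if (which == "volume") sim_volume_core(as.list(full), breath$grid, masks)
    else sim_pressure_core(as.list(full), breath$grid, masks),
    dilvr_error = function(e) NULL)
  if (is.null(sim)) return(PENALTY_MSE)
  mean((sim - (if (which == "volume") breath$volume else breath$pressure))^2)
}

#' Mean-squared-error objective
#'
#' The estimation objective: the mean squared residual between the waveform
#' simulated at `params` and the measured trace. Simulation failures
#' (degenerate normalizations at pathological parameter combinations) yield a
#' large penalty value rather than an error, which keeps multi-start
#' optimization alive.
#'
#' @param params Full named parameter vector or list for the chosen
#'   sub-model (all of `theta, a1, b1, phi1, beta1, beta2, Av` for volume;
#'   the fourteen pressure parameters plus `theta` for pressure).
#' @param breath A [breath_record()].
#' @param which `"volume"` or `"pressure"`.
#' @param masks Mask convention, see [simulate_volume()].
#' @return Scalar MSE (ml^2 or cmH2O^2).
#' @export
dilv_objective <- function(params, breath, which = c("volume", "pressure"),
                           masks = c("corrected", "as-printed")) {
  which <- match.arg(which)
  masks <- match.arg(masks)
  stopifnot(inherits(breath, "breath_record"))
  params <- unlist(params)
  need <- if (which == "volume") VOL_PARS else PRES_PARS
  assert_that(all(need %in% names(params)),
              sprintf("missing parameters: %s",
                      paste(setdiff(need, names(params)), collapse = ", ")))
  mse_for(params[need], breath, which, masks)
}

# init draws: uniform in [center - hw, center + hw] clipped to bounds;
# one row per start, prefix-stable in n_starts for a fixed stream seed.
draw_inits <- function(center, hw, lo, hi, n_starts, stream_seed) {
  p <- length(center)
  lo_i <- pmax(center - hw, lo)
  hi_i <- pmin(center + hw, hi)
  set.seed(stream_seed)
  m <- matrix(NA_real_, n_starts, p, dimnames = list(NULL, names(center)))
  for (i in seq_len(n_starts)) m[i, ] <- lo_i + runif(p) * (hi_i - lo_i)
  m
}

halfwidths_for <- function(spec, center) {
  hw <- spec$halfwidth
  if (length(hw) == 1 && is.null(names(hw))) return(abs(center) * hw)
  out <- abs(center) * 0.3
  out[names(hw)] <- hw
  out
}

run_multistart <- function(objective, center, free, bounds, inits, control) {
  p <- length(free)
  n <- nrow(inits)
  par_mat <- matrix(NA_real_, n, p, dimnames = list(NULL, free))
  mse <- numeric(n)
  conv <- integer(n)
  lo <- bounds[free, "lower"]
  hi <- bounds[free, "upper"]
  parscale <- pmax(abs(center[free]), 0.1)
  # box-respecting wrapper for the derivative-free polish stage
  obj_boxed <- function(par) {
    if (any(par < lo) || any(par > hi)) return(PENALTY_MSE)
    objective(par)
  }
  for (i in seq_len(n)) {
    opt <- optim(inits[i, free], objective, method = "L-BFGS-B",
                 lower = lo, upper = hi,
                 control = list(maxit = control$maxit, factr = control$factr,
                                parscale = parscale))
    # L-BFGS-B with numerical gradients stalls in the long, nearly flat
    # valleys this model has (compensating frequency/phase/gradient changes);
    # a short simplex polish walks the valley floor reliably.
    if (control$polish_maxit > 0 && p > 1) {
      nm <- suppressWarnings(
        optim(opt$par, obj_boxed, method = "Nelder-Mead",
              control = list(maxit = control$polish_maxit, reltol = 1e-12,
                             parscale = parscale)))
      if (nm$value < opt$value) {
        opt$par <- nm$par
        opt$value <- nm$value
      }
    }
    par_mat[i, ] <- opt$par
    mse[i] <- opt$value
    conv[i] <- opt$convergence
  }
  list(par = par_mat, mse = mse, convergence = conv)
}

new_dilv_fit <- function(which, ms, center, free, bounds, inits) {
  converged <- ms$convergence == 0 & ms$mse < PENALTY_MSE
  if (!any(converged)) {
    stop_dilvr(sprintf(
      "estimation failure (%s model): none of %d starts converged (%d hit the degenerate-simulation penalty, %d stopped on optimizer status)",
      which, length(ms$mse), sum(ms$mse >= PENALTY_MSE),
      sum(ms$convergence != 0)), "dilvr_estimation_error")
  }
  best_i <- which.min(ms$mse) # ties: first in seed order
  best <- center
  best[free] <- ms$par[best_i, ]
  med <- apply(ms$par[converged, , drop = FALSE], 2, median)
  sem <- apply(ms$par[converged, , drop = FALSE], 2, sd) / sqrt(sum(converged))
  structure(
    list(which = which, par = ms$par, mse = ms$mse,
         convergence = ms$convergence, converged = converged,
         inits = inits[, free, drop = FALSE],
         free = free, center = center,
         frozen = setdiff(names(center), free),
         bounds = bounds[names(center), , drop = FALSE],
         best = best, best_mse = ms$mse[best_i], best_start = best_i,
         median_params = med, sem_params = sem,
         n_converged = sum(converged)),
    class = "dilv_fit")
}

#' Fit the waveform model to one breath
#'
#' Multi-start, bound-constrained nonlinear least squares. For each start an
#' initialization is drawn uniformly from the configured interval and a local
#' L-BFGS-B optimization of the free parameters is run; the full solution
#' distribution is retained, because its spread (and possible multimodality)
#' is the per-breath uncertainty readout. With the default
#' `theta_mode = "from_volume"`, the respiratory frequency is estimated
#' within the volume fit and then frozen for the pressure fit.
#'
#' @param breath A [breath_record()]; resampled to `spec$dt` if needed.
#' @param spec A [fit_spec()].
#' @return An object of class `dilv_breath_fit`: a list with components
#'   `volume` and `pressure` (each a `dilv_fit` holding the per-start
#'   solution distribution, best solution and median/SEM summaries), plus
#'   `theta` (the frequency used for the pressure fit) and `spec`.
#' @seealso [summary.dilv_fit()], [start_table()], [compare_models()]
#' @export
fit_breath <- function(breath, spec) {
  stopifnot(inherits(breath, "breath_record"), inherits(spec, "fit_spec"))
  if (abs(breath$grid$dt - spec$dt) > 1e-12) {
    breath <- resample_breath(breath, spec$dt)
  }
  set.seed(spec$seed)
  stream <- sample.int(.Machine$integer.max - 1L, 2)

  center_v <- unlist(spec$volume)[VOL_PARS]
  center_p <- unlist(spec$pressure)[PRES_PARS]

  if (spec$theta_mode == "joint") {
    free_u <- union(spec$free$volume, spec$free$pressure)
    center_u <- c(center_v, center_p[setdiff(PRES_PARS, "theta")])
    hw <- halfwidths_for(spec, center_u)
    inits <- draw_inits(center_u, hw, spec$bounds[names(center_u), "lower"],
                        spec$bounds[names(center_u), "upper"],
                        spec$n_starts, stream[1])
    obj <- function(par) {
      full <- center_u
      full[free_u] <- par
      mse_for(full[VOL_PARS], breath, "volume", spec$masks) +
        mse_for(full[PRES_PARS], breath, "pressure", spec$masks)
    }
    ms <- run_multistart(obj, center_u, free_u, spec$bounds, inits, spec$control)
    fit_u <- new_dilv_fit("joint", ms, center_u, free_u, spec$bounds, inits)
    theta_hat <- fit_u$best[["theta"]]
    out <- list(volume = fit_u, pressure = fit_u, joint = fit_u,
                theta = theta_hat, spec = spec, breath = breath)
    class(out) <- "dilv_breath_fit"
    return(out)
  }

  # --- volume fit ---
  free_v <- spec$free$volume
  hw_v <- halfwidths_for(spec, center_v)
  fit_v <- if (length(free_v)) {
    inits_v <- draw_inits(center_v, hw_v, spec$bounds[VOL_PARS, "lower"],
                          spec$bounds[VOL_PARS, "upper"], spec$n_starts, stream[1])
    obj_v <- function(par) {
      full <- center_v
      full[free_v] <- par
      mse_for(full, breath, "volume", spec$masks)
    }
    ms <- run_multistart(obj_v, center_v, free_v, spec$bounds, inits_v, spec$control)
    new_dilv_fit("volume", ms, center_v, free_v, spec$bounds, inits_v)
  } else {
    NULL
  }

  theta_hat <- if (spec$theta_mode == "from_volume" && !is.null(fit_v)) {
    fit_v$best[["theta"]]
  } else {
    center_v[["theta"]]
  }

  # --- pressure fit, theta frozen at the volume estimate ---
  center_p[["theta"]] <- theta_hat
  free_p <- spec$free$pressure
  hw_p <- halfwidths_for(spec, center_p)
  fit_p <- if (length(free_p)) {
    inits_p <- draw_inits(center_p, hw_p, spec$bounds[PRES_PARS, "lower"],
                          spec$bounds[PRES_PARS, "upper"], spec$n_starts, stream[2])
    obj_p <- function(par) {
      full <- center_p
      full[free_p] <- par
      mse_for(full, breath, "pressure", spec$masks)
    }
    ms <- run_multistart(obj_p, center_p, free_p, spec$bounds, inits_p, spec$control)
    new_dilv_fit("pressure", ms, center_p, free_p, spec$bounds, inits_p)
  } else {
    NULL
  }

  structure(list(volume = fit_v, pressure = fit_p, theta = theta_hat,
                 spec = spec, breath = breath),
            class = "dilv_breath_fit")
}

#' @export
print.dilv_fit <- function(x, ...) {
  cat(sprintf("<dilv_fit: %s model> %d/%d starts converged, best MSE = %.6g\n",
              x$which, x$n_converged, length(x$mse), x$best_mse))
  cat("  free:", paste(x$free, collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.dilv_breath_fit <- function(x, ...) {
  cat("<dilv_breath_fit>\n")
  if (!is.null(x$volume)) print(x$volume)
  if (!is.null(x$pressure) && !identical(x$pressure, x$volume)) print(x$pressure)
  cat(sprintf("  theta = %.4g breaths/s; Cd = Av/Ap1 = %.4g ml/cmH2O\n",
              x$theta, unname(x$volume$best["Av"] / x$pressure$best["Ap1"])))
  invisible(x)
}

#' Summarize a multi-start solution distribution
#'
#' Per-parameter median and standard error of the mean over the converged
#' starts, with frozen parameters reported at their fixed values. A parameter
#' is flagged multimodal when its sorted converged solutions contain a gap
#' larger than 10% of the parameter's bound width — the signature of several
#' distinct local optima with similar errors.
#'
#' @param object A `dilv_fit` (one element of [fit_breath()]'s result).
#' @param ... Unused.
#' @return A data frame of class `summary.dilv_fit` with columns `parameter`,
#'   `median`, `sem`, `lo_bound`, `hi_bound`, `frozen`, `multimodal`, and
#'   attributes `mse_best` and `n_converged`.
#' @export
summary.dilv_fit <- function(object, ...) {
  if (object$n_converged < 2) {
    stop_dilvr(sprintf(
      "cannot summarize: only %d converged start(s); at least 2 are required",
      object$n_converged), "dilvr_estimation_error")
  }
  pars <- names(object$center)
  med <- sem <- numeric(length(pars))
  mm <- logical(length(pars))
  names(med) <- names(sem) <- names(mm) <- pars
  med[pars] <- object$center
  for (nm in object$free) {
    sol <- sort(object$par[object$converged, nm])
    med[nm] <- object$median_params[nm]
    sem[nm] <- object$sem_params[nm]
    width <- object$bounds[nm, "upper"] - object$bounds[nm, "lower"]
    mm[nm] <- length(sol) > 1 && max(diff(sol)) > 0.1 * width
  }
  out <- data.frame(
    parameter = pars, median = unname(med), sem = unname(sem),
    lo_bound = unname(object$bounds[pars, "lower"]),
    hi_bound = unname(object$bounds[pars, "upper"]),
    frozen = !(pars %in% object$free),
    multimodal = unname(mm))
  attr(out, "mse_best") <- object$best_mse
  attr(out, "n_converged") <- object$n_converged
  class(out) <- c("summary.dilv_fit", "data.frame")
  out
}

#' @export
print.summary.dilv_fit <- function(x, ...) {
  cat(sprintf("Multi-start fit summary: %d converged starts, best MSE %.6g\n",
              attr(x, "n_converged"), attr(x, "mse_best")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Per-start solution table
#'
#' @param fit A `dilv_fit`.
#' @return Data frame with one row per optimization start: `start_id`, the
#'   fitted free parameters, `mse` and `converged`.
#' @export
start_table <- function(fit) {
  stopifnot(inherits(fit, "dilv_fit"))
  data.frame(start_id = seq_along(fit$mse), fit$par, mse = fit$mse,
             converged = fit$converged)
}

#' Compare the waveform model against the single-compartment model
#'
#' Fits both models to the same breath and returns the ratio of their
#' pressure mean squared errors; values below 1 mean the waveform model
#' reproduces the measured pressure more closely. The comparison is made on
#' the pressure trace because that is the quantity both models predict (the
#' single-compartment model takes volume and flow as inputs).
#'
#' @param breath A [breath_record()].
#' @param spec A [fit_spec()].
#' @param at Evaluate the fitted waveform model at the `"best"` (default) or
#'   `"median"` multi-start solution.
#' @return An object of class `model_comparison`: list with `ratio`,
#'   `mse_dilv` (pressure), `mse_dilv_volume`, `mse_sc`, and the two fits.
#' @export
compare_models <- function(breath, spec, at = c("best", "median")) {
  at <- match.arg(at)
  stopifnot(inherits(breath, "breath_record"))
  dilv <- fit_breath(breath, spec)
  sc <- fit_sc(breath)
  eval_at <- function(fit, which) {
    if (at == "best") return(fit$best_mse)
    full <- fit$center
    full[fit$free] <- fit$median_params
    mse_for(full[if (which == "volume") VOL_PARS else PRES_PARS],
            dilv$breath %||% breath, which, spec$masks)
  }
  mse_p <- eval_at(dilv$pressure, "pressure")
  mse_v <- eval_at(dilv$volume, "volume")
  mse_sc <- max(sc$mse, .Machine$double.eps) # guard: strictly positive denominator
  structure(
    list(ratio = mse_p / mse_sc, mse_dilv = mse_p, mse_dilv_volume = mse_v,
         mse_sc = mse_sc, dilv = dilv, sc = sc, at = at),
    class = "model_comparison")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf(
    "DILV pressure MSE %.6g vs single-compartment %.6g cmH2O^2: ratio = %.4g (%s solution)\n",
    x$mse_dilv, x$mse_sc, x$ratio, x$at))
  invisible(x)
}

# linear-interpolation resampling of a breath onto step dt
resample_breath <- function(breath, dt) {
  t_old <- grid_times(breath$grid)
  t_new <- seq(t_old[1], t_old[length(t_old)], by = dt)
  g <- sample_grid(dt, length(t_new), t_start = t_old[1],
                   burn_in_periods = breath$grid$burn_in_periods)
  res <- function(x) if (is.null(x)) NULL else approx(t_old, x, xout = t_new)$y
  breath_record(g, pressure = res(breath$pressure), volume = res(breath$volume),
                flow = res(breath$flow), meta = breath$meta)
}
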