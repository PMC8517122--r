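#' Synthetic-breath scenario
#'
#' Defines a generating regime for ground-truth test data. Four regimes are
#' provided, mirroring the reference parameter presets ([dilv_presets()]):
#' `"healthy-like"` and `"injured-like"` (mouse-scale pressure-controlled
#' breaths; the injured regime has lower amplitude ratio `Av/Ap1`),
#' `"vd-like"` (human-scale breaths with plateau-pressure peaks, `Ap2 > 0`,
#' as seen with ventilator dyssynchrony) and `"sc-generated"` (pressure
#' produced by the linear single-compartment model from a simulated volume,
#' so that comparator fits are exact by construction).
#'
#' Noise is additive i.i.d. Gaussian per sample with standard deviation
#' `noise_sd` times the peak-to-trough amplitude of the noise-free trace.
#' Breath-to-breath parameter jitter is multiplicative Gaussian:
#' `truth * (1 + jitter * z)`, clipped to the parameter's validity region.
#'
#' @param regime One of `"healthy-like"`, `"injured-like"`, `"vd-like"`,
#'   `"sc-generated"`.
#' @param volume,pressure Optional [volume_params()] / [pressure_params()]
#'   overriding the regime's generating parameters.
#' @param sc Optional [sc_params()] for the `"sc-generated"` regime (default
#'   mouse-scale: E = 33.3 cmH2O/ml, R = 0.6 cmH2O.s/ml, P0 = 3 cmH2O).
#' @param noise_sd Noise standard deviation as a fraction of trace amplitude
#'   (>= 0; default 0.01).
#' @param n_breaths Number of breaths in a cohort (default 1).
#' @param jitter Fractional breath-to-breath parameter perturbation in
#'   \[0, 0.5\] (default 0).
#' @param seed Integer seed; together with the breath index it fully
#'   determines each breath.
#' @param dt Sampling step, s.
#' @param burn_in_periods Warm-up periods for the simulator.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(regime = c("healthy-like", "injured-like", "vd-like",
                                     "sc-generated"),
                          volume = NULL, pressure = NULL, sc = NULL,
                          noise_sd = 0.01, n_breaths = 1, jitter = 0,
                          seed = 1, dt = 0.005, burn_in_periods = 3) {
  regime <- match.arg(regime)
  assert_that(is.numeric(noise_sd) && length(noise_sd) == 1 && noise_sd >= 0,
              "`noise_sd` must be a single nonnegative number")
  assert_that(is.numeric(n_breaths) && length(n_breaths) == 1 && n_breaths >= 1,
              "`n_breaths` must be a positive integer")
  assert_that(is.numeric(jitter) && length(jitter) == 1 && jitter >= 0 &&
                jitter <= 0.5, "`jitter` must lie in [0, 0.5]")
  preset <- switch(regime,
                   "healthy-like" = dilv_presets("healthy_mouse"),
                   "injured-like" = dilv_presets("injured_mouse"),
                   "vd-like" = dilv_presets("human1_begin"),
                   "sc-generated" = dilv_presets("healthy_mouse"))
  volume <- volume %||% preset$volume
  pressure <- pressure %||% preset$pressure
  if (regime == "sc-generated") {
    sc <- sc %||% sc_params(E = 33.3, R = 0.6, P0 = 3)
    stopifnot(inherits(sc, "sc_params"))
  }
  stopifnot(inherits(volume, "volume_params"), inherits(pressure, "pressure_params"))
  structure(
    list(regime = regime, volume = volume, pressure = pressure, sc = sc,
         noise_sd = noise_sd, n_breaths = as.integer(n_breaths),
         jitter = jitter, seed = as.integer(seed), dt = dt,
         burn_in_periods = burn_in_periods),
    class = "scenario_spec")
}

# per-(seed, index) RNG stream: independent of how many breaths are drawn
breath_seed <- function(seed, index) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, index)[index]
}

jitter_params <- function(params, jitter, names_clip_beta, names_clip_b) {
  if (jitter == 0) return(params)
  v <- unlist(unclass(params))
  v <- v * (1 + jitter * rnorm(length(v)))
  v[names_clip_beta] <- pmax(v[names_clip_beta], 1)
  v[names_clip_b] <- pmin(pmax(v[names_clip_b], -0.98), 0.98)
  v
}

#' Generate one synthetic breath with known ground truth
#'
#' @param spec A [scenario_spec()].
#' @param index Breath index (1-based); each `(seed, index)` pair yields a
#'   reproducible breath regardless of generation order.
#' @return A [breath_record()] whose `meta` carries `truth` (the named
#'   generating parameter vector), `regime`, `index` and `noise_sd`.
#' @examples
#' b <- make_breath(scenario_spec("healthy-like", noise_sd = 0))
#' max(b$volume)  # = generating Av
#' @export
make_breath <- function(spec, index = 1) {
  stopifnot(inherits(spec, "scenario_spec"))
  set.seed(breath_seed(spec$seed, index))

  vp <- unlist(unclass(spec$volume))
  pp <- unlist(unclass(spec$pressure))
  if (spec$jitter > 0) {
    vp <- jitter_params(spec$volume, spec$jitter, c("beta1", "beta2"), "b1")
    pp <- jitter_params(spec$pressure, spec$jitter,
                        c("beta3", "beta4", "beta5", "beta6"), "b2")
    pp[["theta"]] <- vp[["theta"]] # coupling survives jitter
    vp["a1"] <- max(vp["a1"], 0.1)
    pp["a2"] <- max(pp["a2"], 0.1)
    pp["a3"] <- max(pp["a3"], 0.1)
    pp[c("Ap2", "Ap3")] <- pmax(pp[c("Ap2", "Ap3")], 0)
  }
  grid <- sample_grid(spec$dt, ceiling(1 / (vp[["theta"]] * spec$dt)),
                      burn_in_periods = spec$burn_in_periods)

  V <- sim_volume_core(as.list(vp), grid)
  truth <- c(vp, pp[setdiff(names(pp), "theta")])
  if (spec$regime == "sc-generated") {
    fl <- derive_flow(V, grid$dt)
    P <- sc_predict_pressure(spec$sc, V, fl)
    truth <- c(vp, E = spec$sc$E, R = spec$sc$R, P0 = spec$sc$P0)
  } else {
    P <- sim_pressure_core(as.list(pp), grid)
  }

  if (spec$noise_sd > 0) {
    V <- V + rnorm(grid$n, 0, spec$noise_sd * diff(range(V)))
    P <- P + rnorm(grid$n, 0, spec$noise_sd * diff(range(P)))
  }
  breath_record(grid, pressure = P, volume = V,
                flow = derive_flow(V, grid$dt),
                meta = list(truth = truth, regime = spec$regime,
                            index = index, noise_sd = spec$noise_sd,
                            seed = spec$seed))
}

#' Generate a cohort of synthetic breaths
#'
#' @param spec A [scenario_spec()] with `n_breaths >= 1`.
#' @return A list of class `breath_cohort`:
#'   * `breaths` — list of [breath_record()]s;
#'   * `truth` — data frame, one row per breath, with `breath_id`, `regime`,
#'     `seed` and the generating parameter values;
#'   * `record` — the breaths concatenated into one continuous record
#'     (class `ventilator_record`) for segmentation tests.
#' @export
make_cohort <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  breaths <- lapply(seq_len(spec$n_breaths), function(i) make_breath(spec, i))
  truth <- do.call(rbind, lapply(breaths, function(b) {
    data.frame(breath_id = b$meta$index, regime = b$meta$regime,
               seed = b$meta$seed, as.list(b$meta$truth))
  }))
  t_all <- numeric(0); p_all <- numeric(0); v_all <- numeric(0)
  offset <- 0
  for (b in breaths) {
    t_all <- c(t_all, grid_times(b$grid) + offset)
    p_all <- c(p_all, b$pressure)
    v_all <- c(v_all, b$volume)
    offset <- offset + b$grid$n * b$grid$dt
  }
  record <- ventilator_record(time = t_all, pressure = p_all, volume = v_all,
                              meta = list(regime = spec$regime, seed = spec$seed,
                                          n_breaths = spec$n_breaths))
  structure(list(breaths = breaths, truth = truth, record = record),
            class = "breath_cohort")
}

#' @export
print.breath_cohort <- function(x, ...) {
  cat(sprintf("<breath_cohort> %d %s breaths, %.3g s total\n",
              length(x$breaths), x$breaths[[1]]$meta$regime,
              max(x$record$time)))
  invisible(x)
}
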