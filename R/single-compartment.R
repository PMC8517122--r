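#' Single-compartment model parameters
#'
#' The classical linear equation of motion of the respiratory system lumps
#' lung mechanics into an elastance and a resistance:
#' `P = E * V + R * V' + P0`. Compliance is the reciprocal of elastance,
#' `C = 1/E`.
#'
#' @param E Elastance, cmH2O/ml.
#' @param R Resistance, cmH2O.s/ml.
#' @param P0 Baseline pressure, cmH2O.
#' @return An object of class `sc_params` with fields `E`, `R`, `P0` and the
#'   derived compliance `C = 1/E`.
#' @export
sc_params <- function(E, R, P0) {
  for (nm in c("E", "R", "P0")) {
    v <- get(nm)
    assert_that(is.numeric(v) && length(v) == 1 && is.finite(v),
                sprintf("`%s` must be a single finite number", nm))
  }
  structure(list(E = E, R = R, P0 = P0, C = 1 / E), class = "sc_params")
}

#' @export
print.sc_params <- function(x, ...) {
  cat(sprintf("<sc_params> E = %.4g cmH2O/ml, R = %.4g cmH2O.s/ml, P0 = %.4g cmH2O (C = %.4g ml/cmH2O)\n",
              x$E, x$R, x$P0, x$C))
  invisible(x)
}

#' Predict pressure from the single-compartment model
#'
#' @param sc An [sc_params()] object.
#' @param volume Volume trace, ml.
#' @param flow Flow trace, ml/s, same length as `volume`.
#' @return Elementwise `E * volume + R * flow + P0`.
#' @export
sc_predict_pressure <- function(sc, volume, flow) {
  stopifnot(inherits(sc, "sc_params"))
  assert_that(is.numeric(volume) && is.numeric(flow) &&
                length(volume) == length(flow),
              "`volume` and `flow` must be numeric vectors of equal length")
  sc$E * volume + sc$R * flow + sc$P0
}

#' Fit the single-compartment model to a breath
#'
#' Ordinary least squares of pressure on volume, flow, and an intercept —
#' the standard way a single compartment is fitted to ventilator data. Flow
#' is derived by central finite differences of volume if absent from the
#' record.
#'
#' @param breath A [breath_record()] with pressure and volume.
#' @return A list of class `sc_fit` with elements `params` ([sc_params()]),
#'   `mse` (mean squared pressure residual, cmH2O^2), `fitted` and
#'   `residuals`.
#' @examples
#' g <- sample_grid(0.005, 667)
#' V <- simulate_volume(volume_params(), g)
#' fl <- c(diff(V)[1], (V[-(1:2)] - V[-c(666:667)]) / 0.01, diff(V)[666]) / 1
#' P <- 2 * V + 0.5 * fl + 3
#' fit <- fit_sc(breath_record(g, P, V, fl))
#' fit$params
#' @export
fit_sc <- function(breath) {
  stopifnot(inherits(breath, "breath_record"))
  breath <- ensure_flow(breath)
  X <- cbind(V = breath$volume, flow = breath$flow, intercept = 1)
  if (qr(X)$rank < 3L) {
    stop_dilvr(
      "degenerate single-compartment fit: regressors [volume, flow, 1] are rank-deficient (constant volume and/or zero flow)",
      "dilvr_degenerate_fit")
  }
  cf <- qr.coef(qr(X), breath$pressure)
  fitted <- drop(X %*% cf)
  res <- breath$pressure - fitted
  structure(
    list(params = sc_params(E = unname(cf["V"]), R = unname(cf["flow"]),
                            P0 = unname(cf["intercept"])),
         mse = mean(res^2), fitted = fitted, residuals = res),
    class = "sc_fit")
}

#' @export
print.sc_fit <- function(x, ...) {
  print(x$params)
  cat(sprintf("  pressure MSE = %.6g cmH2O^2\n", x$mse))
  invisible(x)
}
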