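test_that("volume model: periodic, nonnegative, amplitude-normalized", {
  g <- grid_for(0.3, periods = 3)
  V <- simulate_volume(volume_params(), g) # reference shape parameters
  expect_true(all(V >= 0))
  expect_equal(max(V), 1, tolerance = 1e-3)
  # periodic with period 1/theta (grid chosen with integer samples/period)
  gp <- grid_for(0.25, periods = 3)
  Vp <- simulate_volume(volume_params(theta = 0.25), gp)
  shift <- round(1 / 0.25 / gp$dt)
  expect_lt(max(abs(Vp[1:(gp$n - shift)] - Vp[(shift + 1):gp$n])), 1e-4 * max(Vp))
  # amplitude scaling
  expect_equal(simulate_volume(volume_params(Av = 0), g), rep(0, g$n))
  expect_equal(simulate_volume(volume_params(Av = 2.5), g), 2.5 * V)
})

test_that("volume rise and fall gradients are controlled monotonically by beta1/beta2", {
  g <- sample_grid(0.001, 3334) # dense oracle grid over one period
  base <- function(...) simulate_volume(volume_params(...), g)
  # doubling beta1 strictly increases the time to 95% of peak
  t95 <- vapply(c(30, 60), function(b1) rise_time_to(base(beta1 = b1), g$dt), 0)
  expect_lt(t95[1], t95[2])
  # 10-point sweeps: rise time nondecreasing in beta1, fall time in beta2
  rise <- vapply(seq(10, 100, length.out = 10),
                 function(b) rise_time_to(base(beta1 = b), g$dt), 0)
  expect_true(all(diff(rise) >= 0))
  fall <- vapply(seq(5, 50, length.out = 10), function(b) {
    V <- base(beta2 = b)
    i_peak <- which.max(V)
    g$dt * (which(V[i_peak:g$n] <= 0.05 * max(V))[1] - 1)
  }, 0)
  expect_true(all(diff(fall) >= 0))
})

test_that("increasing b1 shortens the inspiratory fraction of the cycle", {
  g <- grid_for(0.3, periods = 4)
  insp_frac <- vapply(c(-0.5, 0, 0.3, 0.7, 0.9), function(b1) {
    Vc <- simulate_volume(volume_params(a1 = 200, b1 = b1), g, components = TRUE)
    mean(Vc$fb1 > 0.5)
  }, 0)
  expect_true(all(diff(insp_frac) < 0))
  # and matches the analytic duty fraction for the sharp drive
  expect_equal(insp_frac[4], duty_fraction(0.7), tolerance = 2 / (0.3 * g$n * g$dt * 100))
})

test_that("degenerate feature configurations surface as normalization errors", {
  g <- grid_for(0.25)
  expect_error(volume_params(b1 = 1.2), class = "dilvr_invalid_parameter")
  # low-volume pulse placed entirely inside the plateau, where the main
  # component already saturates to 1: the knee term has nothing to normalize
  p_bad <- pressure_params(theta = 0.25, a2 = 5000, b2 = 0, phi2 = 0,
                           a3 = 5000, b3 = 0.9, phi3 = 0,
                           beta3 = 1, beta4 = 1, Ap3 = 0.5)
  expect_error(simulate_pressure(p_bad, g),
               class = "dilvr_degenerate_normalization")
})

test_that("pressure model components behave as feature switches", {
  g <- grid_for(0.3, periods = 3)
  pc <- simulate_pressure(pressure_params(), g, components = TRUE) # reference shape
  # components peak at their amplitude parameters
  expect_equal(max(pc$fp13), 1, tolerance = 1e-3)   # Ap1
  expect_equal(max(pc$fp24), 0.5, tolerance = 1e-12) # Ap2 exactly, by normalization
  expect_equal(max(pc$fp33), 0.5, tolerance = 1e-12) # Ap3 exactly
  # baseline bound
  expect_gt(min(pc$P), 0 - 0.02 * (1 + 0.5 + 0.5))
  # switching off the plateau peaks / knee removes them exactly
  p0 <- simulate_pressure(pressure_params(Ap2 = 0), g, components = TRUE)
  expect_identical(p0$fp24, rep(0, g$n))
  p0 <- simulate_pressure(pressure_params(Ap3 = 0), g, components = TRUE)
  expect_identical(p0$fp33, rep(0, g$n))
  # baseline only
  expect_equal(simulate_pressure(pressure_params(Ap1 = 0, Ap2 = 0, Ap3 = 0, Ap4 = 7), g),
               rep(7, g$n))
})

test_that("plateau-peak feature produces two peaks per plateau and reference shape is periodic", {
  g <- grid_for(0.3, periods = 3)
  pc <- simulate_pressure(pressure_params(), g, components = TRUE)
  # rectangular drive high = plateau; peaks at its beginning and end
  plateau <- pc$fb2 > 0.5
  expect_equal(count_peaks_above(pc$fp24, 0.25) / 3, 2, tolerance = 0.4)
  expect_gt(mean(pc$fp24[plateau]), mean(pc$fp24[!plateau]))
  gp <- grid_for(0.25, periods = 3)
  Pp <- simulate_pressure(pressure_params(theta = 0.25), gp)
  shift <- round(1 / 0.25 / gp$dt)
  expect_lt(max(abs(Pp[1:(gp$n - shift)] - Pp[(shift + 1):gp$n])),
            1e-4 * diff(range(Pp)))
})

test_that("pressure rise/fall gradients are controlled monotonically by beta3/beta4", {
  g <- sample_grid(0.001, 3334)
  prise <- vapply(seq(2, 40, length.out = 10), function(b) {
    P <- simulate_pressure(pressure_params(beta3 = b, Ap2 = 0, Ap3 = 0), g)
    rise_time_to(P, g$dt)
  }, 0)
  expect_true(all(diff(prise) >= 0))
  pfall <- vapply(seq(2, 40, length.out = 10), function(b) {
    P <- simulate_pressure(pressure_params(beta4 = b, Ap2 = 0, Ap3 = 0), g)
    i_peak <- which.max(P)
    g$dt * (which(P[i_peak:g$n] <= 0.05 * max(P))[1] - 1)
  }, 0)
  expect_true(all(diff(pfall) >= 0))
})

test_that("as-printed mask mode is available and suppresses the expiratory segment", {
  g <- grid_for(0.3)
  corrected <- simulate_volume(volume_params(), g, components = TRUE)
  printed <- simulate_volume(volume_params(), g, masks = "as-printed",
                             components = TRUE)
  # as printed, the expiratory term is masked by the inspiratory drive, so it
  # vanishes where the corrected term carries the falling signal
  exp_win <- corrected$fb1 < 0.01
  expect_gt(max(corrected$fv2[exp_win]), 0.5)
  expect_lt(max(printed$fv2[exp_win]), 0.05)
})

test_that("combined breath couples the models through theta and carries consistent flow", {
  hm <- dilv_presets("healthy_mouse")
  g <- grid_for(0.66, periods = 1)
  b <- simulate_breath(hm$volume, hm$pressure, g)
  expect_s3_class(b, "breath_record")
  expect_equal(max(b$volume), 1.03, tolerance = 0.01)
  expect_equal(max(b$pressure), 35.53 + 0.06, tolerance = 0.02 * 35.59)
  # flow re-integrates to volume within discretization error
  v_back <- b$volume[1] + cumsum(c(0, (b$flow[-1] + b$flow[-g$n]) / 2 * g$dt))
  expect_lt(max(abs(v_back - b$volume)), 0.01 * max(b$volume))
  # mismatched frequencies are a coupling violation
  expect_error(
    simulate_breath(volume_params(theta = 0.3), pressure_params(theta = 0.4), g),
    class = "dilvr_coupling_error")
})

test_that("fast simulation path agrees with the reference component path", {
  # the fused simulator used during estimation must reproduce the
  # term-by-term reference construction for every bundled parameter set
  for (pre in dilv_presets()) {
    g <- dilvr:::period_grid(pre$volume$theta)
    for (mk in c("corrected", "as-printed")) {
      Vr <- simulate_volume(pre$volume, g, masks = mk, components = TRUE)$V
      Vf <- simulate_volume(pre$volume, g, masks = mk)
      expect_lt(max(abs(Vr - Vf)), 1e-9 * max(abs(Vr)) + 1e-12)
      Pr <- simulate_pressure(pre$pressure, g, masks = mk, components = TRUE)$P
      Pf <- simulate_pressure(pre$pressure, g, masks = mk)
      expect_lt(max(abs(Pr - Pf)), 1e-9 * max(abs(Pr)) + 1e-12)
    }
  }
})

test_that("model-derived compliance is the amplitude ratio with guards", {
  expect_equal(round(dilv_compliance(1.03, 35.53)$Cd, 3), 0.029)
  expect_equal(round(dilv_compliance(0.70, 35.02)$Cd, 3), 0.020)
  expect_equal(round(dilv_compliance(402.61, 16.58)$Cd, 2), 24.28)
  expect_equal(round(dilv_compliance(337.08, 11.64)$Cd, 2), 28.96)
  expect_equal(dilv_compliance(0, 5)$Cd, 0)
  expect_error(dilv_compliance(1, 0), class = "dilvr_invalid_parameter")
})

test_that("parameter registry counts and preset directions are as designed", {
  reg <- dilv_parameters()
  expect_equal(sum(reg$model == "shared"), 1)
  expect_equal(sum(reg$model == "volume"), 6)
  expect_equal(sum(reg$model == "pressure"), 14)
  expect_setequal(reg$name[reg$model == "volume"],
                  c("a1", "b1", "phi1", "beta1", "beta2", "Av"))
  # constructors expose exactly the registry's parameters
  expect_setequal(names(volume_params()), c("theta", reg$name[reg$model == "volume"]))
  expect_setequal(names(pressure_params()), c("theta", reg$name[reg$model == "pressure"]))
  # injured lung has lower amplitude-ratio compliance than healthy
  hm <- dilv_presets("healthy_mouse"); im <- dilv_presets("injured_mouse")
  expect_lt(im$volume$Av / im$pressure$Ap1, hm$volume$Av / hm$pressure$Ap1)
})
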