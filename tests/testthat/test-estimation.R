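test_that("objective is zero at the generating parameters and quadratic in Av", {
  b0 <- make_breath(scenario_spec("healthy-like", noise_sd = 0))
  pre <- dilv_presets("healthy_mouse")
  vp <- unlist(unclass(pre$volume))
  expect_lt(dilv_objective(vp, b0, "volume"), 1e-12)
  pp <- unlist(unclass(pre$pressure))
  expect_lt(dilv_objective(pp, b0, "pressure"), 1e-12)
  # shifting Av by delta raises the objective by delta^2 * mean(normalized shape^2)
  shape2 <- mean((b0$volume / vp[["Av"]])^2)
  for (delta in c(-0.1, 0.05, 0.2)) {
    vp2 <- vp; vp2[["Av"]] <- vp[["Av"]] + delta
    expect_equal(dilv_objective(vp2, b0, "volume"), delta^2 * shape2,
                 tolerance = 1e-8)
  }
})

test_that("objective at the truth approximates the noise variance", {
  # Monte-Carlo: with additive noise, MSE at the generating parameters ~ sigma^2
  pre <- dilv_presets("healthy_mouse")
  vp <- unlist(unclass(pre$volume))
  sp <- scenario_spec("healthy-like", noise_sd = 0.01, n_breaths = 100, seed = 3)
  amp <- diff(range(make_breath(scenario_spec("healthy-like", noise_sd = 0))$volume))
  sigma2 <- (0.01 * amp)^2
  mses <- vapply(1:100, function(i) dilv_objective(vp, make_breath(sp, i), "volume"), 0)
  expect_equal(mean(mses), sigma2, tolerance = 0.1)
})

test_that("objective returns a penalty (not an error) for degenerate simulations", {
  b <- make_breath(scenario_spec("healthy-like", noise_sd = 0))
  pp <- unlist(unclass(pressure_params(theta = 0.66, a2 = 5000, b2 = 0, phi2 = 0,
                                       a3 = 5000, b3 = 0.9, phi3 = 0,
                                       beta3 = 1, beta4 = 1, Ap3 = 0.5)))
  expect_equal(dilv_objective(pp, b, "pressure"), 1e12)
})

test_that("multi-start fit recovers a noise-free breath and is deterministic", {
  b <- make_breath(scenario_spec("healthy-like", noise_sd = 0))
  pre <- dilv_presets("healthy_mouse")
  spec <- spec_at_truth(pre, n_starts = 8, seed = 5, halfwidth = 0.1,
                        control = list(polish_maxit = 500))
  fit <- fit_breath(b, spec)
  truth <- c(unlist(unclass(pre$volume)), unlist(unclass(pre$pressure)))
  for (nm in spec$free$volume) {
    expect_equal(fit$volume$median_params[[nm]], truth[[nm]], tolerance = 1e-3,
                 label = sprintf("volume median %s", nm))
  }
  expect_lt(fit$volume$best_mse, 1e-8 * max(b$volume)^2)
  expect_lt(fit$pressure$best_mse, 1e-6 * max(b$pressure)^2)
  # determinism: identical (breath, spec, seed) -> identical distributions
  fit2 <- fit_breath(b, spec)
  expect_identical(fit$volume$par, fit2$volume$par)
  expect_identical(fit$pressure$mse, fit2$pressure$mse)
  # frozen parameters are returned unchanged, bit for bit
  expect_identical(fit$volume$best[["a1"]], pre$volume$a1)
  expect_identical(fit$pressure$best[["a3"]], pre$pressure$a3)
  expect_identical(fit$pressure$best[["Ap2"]], pre$pressure$Ap2)
})

test_that("best MSE is nonincreasing in the number of starts for a fixed seed", {
  b <- make_breath(scenario_spec("healthy-like", noise_sd = 0.01, seed = 2))
  pre <- dilv_presets("healthy_mouse")
  mse_k <- vapply(c(2, 4, 8), function(k) {
    fit_breath(b, spec_at_truth(pre, n_starts = k, seed = 31))$volume$best_mse
  }, 0)
  expect_true(all(diff(mse_k) <= 1e-15))
})

test_that("theta modes: frozen theta stays fixed; volume estimate feeds the pressure fit", {
  b <- make_breath(scenario_spec("healthy-like", noise_sd = 0.005, seed = 4))
  pre <- dilv_presets("healthy_mouse")
  spec_fx <- spec_at_truth(pre, n_starts = 3, seed = 9, theta_mode = "fixed")
  fit_fx <- fit_breath(b, spec_fx)
  expect_false("theta" %in% fit_fx$volume$free)
  expect_identical(fit_fx$theta, pre$volume$theta)
  spec_fv <- spec_at_truth(pre, n_starts = 3, seed = 9)
  fit_fv <- fit_breath(b, spec_fv)
  expect_identical(fit_fv$pressure$best[["theta"]], fit_fv$volume$best[["theta"]])
})

test_that("summary reports median/sem, frozen flags and multimodality", {
  b <- make_breath(scenario_spec("healthy-like", noise_sd = 0.005, seed = 6))
  pre <- dilv_presets("healthy_mouse")
  fit <- fit_breath(b, spec_at_truth(pre, n_starts = 6, seed = 10))
  s <- summary(fit$volume)
  expect_setequal(s$parameter, names(unlist(unclass(pre$volume))))
  expect_true(all(s$sem[s$frozen] == 0))
  expect_true(all(s$sem[!s$frozen] >= 0))
  expect_equal(attr(s, "n_converged"), fit$volume$n_converged)

  # all-identical starts give SEM zero
  f0 <- fit$volume
  f0$par[] <- rep(f0$par[1, ], each = nrow(f0$par))
  f0$converged[] <- TRUE
  f0$median_params <- f0$par[1, ]
  f0$sem_params <- apply(f0$par, 2, sd) / sqrt(nrow(f0$par))
  expect_true(all(summary(f0)$sem == 0))

  # constructed bimodal distribution trips the multimodality flag
  f1 <- fit$volume
  f1$bounds["Av", ] <- c(0, 200)
  f1$par[, "Av"] <- rep(c(1, 90), length.out = nrow(f1$par)) # two clusters
  f1$median_params["Av"] <- median(f1$par[f1$converged, "Av"])
  f1$sem_params["Av"] <- sd(f1$par[f1$converged, "Av"]) / sqrt(f1$n_converged)
  s1 <- summary(f1)
  expect_true(s1$multimodal[s1$parameter == "Av"])

  # too few converged starts is an estimation error
  f2 <- fit$volume
  f2$converged[] <- FALSE
  f2$converged[1] <- TRUE
  f2$n_converged <- 1
  expect_error(summary(f2), class = "dilvr_estimation_error")
})

test_that("parameter recovery at 1% noise stays within 5% for the identifiable set", {
  # human-scale breath with all default-free parameters well above the noise
  pre <- dilv_presets("human1_begin")
  sp <- scenario_spec("vd-like", noise_sd = 0.01, seed = 12)
  b <- make_breath(sp, 1)
  spec <- spec_at_truth(pre, n_starts = 12, seed = 13)
  fit <- fit_breath(b, spec)
  truth <- c(unlist(unclass(pre$volume)), unlist(unclass(pre$pressure)))
  for (nm in c("Av", "beta1", "beta2", "Ap1", "Ap4")) {
    model <- if (nm %in% c("Av", "beta1", "beta2")) "volume" else "pressure"
    est <- fit[[model]]$median_params[[nm]]
    expect_lt(abs(est - truth[[nm]]) / abs(truth[[nm]]), 0.05,
              label = sprintf("median relative error of %s", nm))
  }
})

test_that("model comparison: near-unity on self-generated linear data, below one with plateau peaks", {
  pre <- dilv_presets("healthy_mouse")
  # single-compartment-generated breath: the comparator is exact on its own data
  b_sc <- make_breath(scenario_spec("sc-generated", noise_sd = 0))
  cmp <- compare_models(b_sc, spec_at_truth(pre, n_starts = 4, seed = 21))
  expect_lt(cmp$mse_sc, 1e-12)
  expect_gt(cmp$ratio, 0) # defined, positive denominator enforced
  # dyssynchrony-like breath: plateau peaks defeat the linear model
  hp <- dilv_presets("human1_begin")
  b_vd <- make_breath(scenario_spec("vd-like", noise_sd = 0.01, seed = 22))
  free_vd <- list(volume = c("theta", "b1", "phi1", "beta1", "beta2", "Av"),
                  pressure = c("b2", "phi2", "beta3", "beta4", "beta5", "beta6",
                               "Ap1", "Ap2", "Ap4"))
  spec_vd <- fit_spec(hp$volume, hp$pressure, free = free_vd, n_starts = 6,
                      seed = 23)
  cmp_vd <- compare_models(b_vd, spec_vd)
  expect_lt(cmp_vd$ratio, 1)
})
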