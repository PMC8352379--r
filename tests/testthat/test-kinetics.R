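test_that("noiseless first-order traces are recovered exactly", {
  cam <- camera_model(noise_sd = 0)
  for (truth in list(c(30, 70, 40), c(29, 87, 31.3), c(31, 60, 68))) {
    tr <- simulate_trace(fixed_params(truth[1], truth[2], truth[3]), cam,
                         exposure_s = 90, seed = 1)
    fit <- fit_first_order(tr)
    expect_true(fit$converged)
    expect_lt(abs(fit$t0_hat - truth[1]) / truth[1], 1e-6)
    expect_lt(abs(fit$tinf_hat - truth[2]) / truth[2], 1e-6)
    expect_lt(abs(fit$tau_hat - truth[3]) / truth[3], 1e-6)
    expect_equal(fit$r_squared, 1, tolerance = 1e-9)
    expect_lt(fit$rmse, 1e-6)
    # CI bounds bracket the estimates
    expect_true(all(fit$ci95[, "low"] <= c(fit$t0_hat, fit$tinf_hat, fit$tau_hat)))
    expect_true(all(fit$ci95[, "high"] >= c(fit$t0_hat, fit$tinf_hat, fit$tau_hat)))
  }
})

test_that("degenerate traces are flagged, not fitted", {
  flat <- temperature_trace(times = 0:10, temp_mean = rep(40, 11))
  fit <- fit_first_order(flat)
  expect_false(fit$converged)
  expect_equal(fit$reason, "degenerate span")
  expect_true(is.na(fit$tau_hat))
  expect_error(fit_first_order(temperature_trace(0:3, c(30, 40, 50, 60))),
               "at least 5 points")
})

test_that("fitted SSE never exceeds the separable grid-search oracle", {
  cam <- camera_model(noise_sd = 0.5)
  for (s in 1:5) {
    tr <- simulate_trace(fixed_params(30, 70, 40), cam, exposure_s = 90,
                         seed = 100 + s)
    fit <- fit_first_order(tr)
    oracle <- grid_search_first_order(fit$times, fit$observed)
    expect_lte(fit$sse, oracle$sse * (1 + 1e-6))
    expect_lt(abs(fit$tau_hat - oracle$tau), 0.05)
  }
})

test_that("fits are shift- and time-unit-equivariant", {
  tr <- simulate_trace(fixed_params(30, 70, 40), camera_model(noise_sd = 0.7),
                       exposure_s = 90, seed = 21)
  fit <- fit_first_order(tr)

  shifted <- temperature_trace(tr$times, tr$temp_mean + 7, tr$temp_sd)
  fit_s <- fit_first_order(shifted)
  expect_equal(fit_s$t0_hat, fit$t0_hat + 7, tolerance = 1e-6)
  expect_equal(fit_s$tinf_hat, fit$tinf_hat + 7, tolerance = 1e-6)
  expect_equal(fit_s$tau_hat, fit$tau_hat, tolerance = 1e-6)
  expect_equal(fit_s$r_squared, fit$r_squared, tolerance = 1e-9)

  scaled <- temperature_trace(tr$times * 3, tr$temp_mean, tr$temp_sd)
  fit_k <- fit_first_order(scaled)
  expect_equal(fit_k$tau_hat, fit$tau_hat * 3, tolerance = 1e-6)
})

test_that("prediction evaluates the fitted step response", {
  tr <- simulate_trace(fixed_params(30, 70, 40), camera_model(noise_sd = 0),
                       exposure_s = 90, seed = 3)
  fit <- fit_first_order(tr)
  expect_equal(predict(fit, 0), fit$t0_hat)
  expect_equal(predict(fit, 1e9), fit$tinf_hat)
  # at t = tau the span is 63.21% covered
  expect_equal(predict(fit, fit$tau_hat),
               fit$tinf_hat - (fit$tinf_hat - fit$t0_hat) * exp(-1))
  flat <- fit_first_order(temperature_trace(0:10, rep(40, 11)))
  expect_error(predict(flat, 0), "non-converged")
})

test_that("tau confidence intervals are calibrated at the study noise level", {
  cam <- camera_model(noise_sd = 0.7)
  hits <- 0L
  taus <- numeric(300)
  for (i in 1:300) {
    tr <- simulate_trace(fixed_params(30, 70, 40), cam, exposure_s = 90,
                         seed = animal_seed(17, "ci", i))
    fit <- fit_first_order(tr)
    taus[i] <- fit$tau_hat
    if (fit$ci95["tau", "low"] <= 40 && fit$ci95["tau", "high"] >= 40)
      hits <- hits + 1L
  }
  coverage <- hits / 300
  expect_gte(coverage, 0.90)
  expect_lte(coverage, 0.99)
  expect_lt(abs(mean(taus) - 40) / 40, 0.02)  # bias within 2%
})

test_that("normalized heating curves span [0, 1] with the right shape", {
  tr <- simulate_trace(fixed_params(30, 70, 40), camera_model(noise_sd = 0),
                       exposure_s = 90, seed = 5)
  nt <- normalized_temperature(tr)
  expect_equal(min(nt$t_tilde), 0)
  expect_equal(max(nt$t_tilde), 1)
  expect_equal(nt$t_tilde[1], 0)                       # monotone start
  expect_equal(nt$t_tilde[length(nt$t_tilde)], 1)      # monotone end
  # closed-form value at t = tau for a 90 s window
  k <- which(tr$times == 40)
  expect_equal(nt$t_tilde[k], (1 - exp(-1)) / (1 - exp(-90 / 40)),
               tolerance = 1e-9)
  expect_equal(round(nt$t_tilde[k], 4), 0.7066)

  # midpoint maps to 0.5
  tr2 <- temperature_trace(0:4, c(10, 12, 15, 18, 20))
  expect_equal(normalized_temperature(tr2)$t_tilde[3], 0.5)

  expect_error(normalized_temperature(temperature_trace(0:4, rep(35, 5))),
               "zero temperature span")
})
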