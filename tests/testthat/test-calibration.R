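test_that("the log-quadratic objective behaves as specified", {
  expect_equal(objective(c(10, 20), c(10, 20)), 0)
  expect_equal(objective(exp(1) * 5, 5), 1, tolerance = 1e-12)
  expect_equal(objective(c(2, 0.5), c(1, 1)), 2 * log(2)^2,
               tolerance = 1e-12)
  expect_equal(objective(c(2, 0.5), c(1, 1)), 0.9609, tolerance = 1e-4)
  # non-positive predictions are penalised, not fatal
  expect_gte(objective(c(-1, 5), c(1, 5)), 1e6)
})

test_that("golden-section search finds a quadratic minimum deterministically", {
  f <- function(x) (x - 3)^2
  fit <- fit_scalar(f, 0.01, 10, tol = 1e-6, log_scale = FALSE)
  expect_equal(fit$par, 3, tolerance = 1e-4)
  expect_true(fit$converged)
  fit2 <- fit_scalar(f, 0.01, 10, tol = 1e-6, log_scale = FALSE)
  expect_identical(fit, fit2)
  # log-scale search on a positive-only objective
  fitl <- fit_scalar(function(x) (log(x) - log(0.02))^2, 1e-4, 1, tol = 1e-5)
  expect_equal(fitl$par, 0.02, tolerance = 1e-3)
  # monotone objective: optimum at an endpoint draws a warning
  expect_warning(fit_scalar(function(x) x, 1, 2, tol = 1e-3), "bracket")
})

test_that("fitted clearance is consistent with the Dose/AUC identity", {
  d <- calibrated()$drug
  # AUCinf = 1000 * Dose / CL; the 0-72 h truncation correction is < 10%
  implied_auc <- 1000 * 2.97 / d$cl_renal_adult_l_h
  expect_lt(abs(implied_auc - 682) / 682, 0.10)
})

test_that("noise-free synthetic observations return the true parameters", {
  truth <- calibrated()$drug
  d <- recovery_noise_free()$drug
  expect_equal(d$cl_renal_adult_l_h, truth$cl_renal_adult_l_h,
               tolerance = 0.02)
  expect_equal(d$peff_cm_min, truth$peff_cm_min, tolerance = 0.02)
  # functional recovery of the slow phase: predicted troughs match truth
  m_fit <- build_model(reference_adult(), d)
  m_true <- build_model(reference_adult(), truth)
  tr_fit <- troughs(simulate_regimen(m_fit, regimen("oral", 20, n_doses = 10),
                                     240, rtol = 1e-6, atol = 1e-8))
  tr_true <- troughs(simulate_regimen(m_true,
                                      regimen("oral", 20, n_doses = 10),
                                      240, rtol = 1e-6, atol = 1e-8))
  expect_equal(tr_fit, tr_true, tolerance = 0.02)
})

test_that("parameters are recovered within 10% under 15% residual noise", {
  truth <- calibrated()$drug
  d <- recovery_noisy()$drug
  expect_equal(d$cl_renal_adult_l_h, truth$cl_renal_adult_l_h,
               tolerance = 0.10)
  expect_equal(d$peff_cm_min, truth$peff_cm_min, tolerance = 0.10)
})

test_that("the packaged observation file matches the built-in table", {
  obs <- reference_observations()
  expect_setequal(obs$label, pedpbpk:::.reference_observations_df()$label)
  expect_equal(obs$value[obs$label == "cmin_day1"], 8.40)
  expect_equal(obs$value[obs$label == "cmin_day10"], 12.79)
  # synthetic sets share the schema
  synth <- obs_noise_free()
  expect_identical(synth[, c("label", "metric")], obs[, c("label", "metric")])
})
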