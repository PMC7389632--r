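test_that("the assembled system has the expected state space", {
  m <- build_model(reference_adult(), test_drug())
  expect_equal(dim(m$A), c(21, 21))
  res <- simulate_regimen(m, regimen("oral", 20), 24)
  expect_equal(ncol(res$amounts_mg), 21)
  expect_true(all(res$amounts_mg > -1e-9))
})

test_that("mass is conserved to 1e-6 across routes and regimens", {
  m <- build_model(reference_adult(), test_drug())
  expect_lt(mass_balance(simulate_regimen(m, regimen("iv_bolus", 2.97), 72)),
            1e-6)
  expect_lt(mass_balance(simulate_regimen(m, regimen("oral", 20), 120)), 1e-6)
  expect_lt(mass_balance(simulate_regimen(m, regimen("oral", 20, n_doses = 3),
                                          72)), 1e-6)
})

test_that("IV exposure obeys the Dose/CL identity for linear elimination", {
  drug <- test_drug()
  m <- build_model(reference_adult(), drug)
  res <- simulate_regimen(m, regimen("iv_bolus", 2.97), 480, dt_out_h = 0.01)
  s <- pk_summary(res)
  expect_equal(s$auc_inf_ng_h_ml, 1000 * 2.97 / drug$cl_renal_adult_l_h,
               tolerance = 5e-3)
  expect_equal(s$tmax_h, 0)  # monotone decline after a bolus
})

test_that("exposure is strictly proportional to dose", {
  m <- build_model(reference_adult(), test_drug())
  r1 <- simulate_regimen(m, regimen("oral", 10), 120)
  r2 <- simulate_regimen(m, regimen("oral", 20), 120)
  dev <- max(abs(r2$plasma_conc_ng_ml - 2 * r1$plasma_conc_ng_ml)) /
    max(r2$plasma_conc_ng_ml)
  expect_lt(dev, 1e-6)
})

test_that("multiple dosing equals superposition of shifted single doses", {
  m <- build_model(reference_adult(), test_drug())
  multi <- simulate_regimen(m, regimen("oral", 20, n_doses = 10), 240)
  single <- simulate_regimen(m, regimen("oral", 20), 240)
  shift <- round(24 / 0.05)
  n <- length(single$time_h)
  super <- numeric(n)
  for (k in 0:9) {
    idx <- seq_len(n - k * shift)
    super[idx + k * shift] <- super[idx + k * shift] +
      single$plasma_conc_ng_ml[idx]
  }
  dev <- max(abs(multi$plasma_conc_ng_ml - super)) /
    max(multi$plasma_conc_ng_ml)
  expect_lt(dev, 1e-6)
})

test_that("without permeability an oral dose is excreted entirely in feces", {
  drug <- test_drug(peff_cm_min = 0)
  m <- build_model(reference_adult(), drug)
  res <- simulate_regimen(m, regimen("oral", 20), 400)
  n <- length(res$time_h)
  expect_lt(res$cumulative_urine_mg[n], 1e-9)
  expect_equal(res$cumulative_feces_mg[n], 20, tolerance = 1e-4)
  expect_true(all(res$plasma_conc_ng_ml < 1e-12))
})

test_that("fast-perfusion limit collapses to one-compartment kinetics", {
  adult <- reference_adult()
  drug <- test_drug(deep_kin_per_h = 0, deep_kout_per_h = 1,
                    kp_scalar = solve_kp_scalar(0.89, adult, 0, 1))
  m <- build_model(adult, drug, q_mult = 1e3)
  res <- simulate_regimen(m, regimen("iv_bolus", 2.97), 72)
  vss <- 0.89 * adult$weight_kg
  cl <- drug$cl_renal_adult_l_h
  sel <- res$time_h >= 0.05
  analytic <- 1000 * 2.97 / vss * exp(-cl * res$time_h[sel] / vss)
  rel <- (res$plasma_conc_ng_ml[sel] - analytic) / analytic
  expect_lt(sqrt(mean(rel^2)), 0.005)
})

test_that("a meal delays gastric emptying and only gastric emptying", {
  m <- build_model(reference_adult(), test_drug())
  expect_identical(apply_fed_state(m, 0)$A, m$A)
  fed <- apply_fed_state(m, 524)
  expect_equal(fed$k_ge, m$k_ge / (1 + m$drug$fed_alpha), tolerance = 1e-12)
  changed <- which(fed$A != m$A, arr.ind = TRUE)
  touched <- unique(rownames(m$A)[changed[, 1]])
  expect_setequal(touched, c("stom_sol", "stom_dis", "duo_sol", "duo_dis"))
  expect_error(apply_fed_state(m, -1), "non-negative")
})

test_that("food slows absorption but leaves bioavailability unaffected", {
  m <- build_model(reference_adult(), test_drug())
  fast <- pk_summary(simulate_regimen(m, regimen("oral", 20), 120))
  fed <- pk_summary(simulate_regimen(m, regimen("oral", 20, fed = TRUE), 120))
  expect_gt(fed$tmax_h, fast$tmax_h)
  expect_lt(fed$cmax_ng_ml, fast$cmax_ng_ml)
  expect_gt(fed$auc_inf_ng_h_ml / fast$auc_inf_ng_h_ml, 0.9)
  expect_lt(fed$auc_inf_ng_h_ml / fast$auc_inf_ng_h_ml, 1.1)
})

test_that("population aggregation preserves pointwise ordering", {
  drug <- test_drug()
  pop1 <- sample_population(population_spec(1, 0, 29, 29, seed = 3))
  ps1 <- simulate_population(pop1, drug, reg = regimen("oral", 20),
                             t_end_h = 48, rtol = 1e-6, atol = 1e-8)
  expect_equal(ps1$mean, ps1$min, tolerance = 1e-12)
  expect_equal(ps1$mean, ps1$max, tolerance = 1e-12)
  pop <- sample_population(population_spec(8, 0.5, 21, 37, seed = 4))
  ps <- simulate_population(pop, drug, reg = regimen("oral", 20),
                            t_end_h = 48, rtol = 1e-6, atol = 1e-8)
  expect_true(all(ps$min <= ps$p05 + 1e-12))
  expect_true(all(ps$p05 <= ps$p95 + 1e-12))
  expect_true(all(ps$p95 <= ps$max + 1e-12))
  expect_true(all(ps$min - 1e-12 <= ps$mean & ps$mean <= ps$max + 1e-12))
  expect_equal(nrow(ps$subjects), 8)
})
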