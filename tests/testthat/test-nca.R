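test_that("trapezoidal AUC reproduces closed-form cases", {
  tt <- seq(0, 120, 0.05)
  expect_equal(auc_trapz(tt, rep(10, length(tt)), 0, 120), 1200,
               tolerance = 1e-12)
  expect_equal(auc_trapz(c(0, 1), c(0, 2), 0, 1), 1, tolerance = 1e-12)
  tt <- seq(0, 120, 0.01)
  cc <- 100 * exp(-0.1 * tt)
  analytic <- 1000 * (1 - exp(-12))
  expect_equal(auc_trapz(tt, cc, 0, 120), analytic, tolerance = 1e-4)
  expect_error(auc_trapz(c(0, 1), c(1, 1), 0, 2), "outside")
})

test_that("AUC is exactly additive over adjacent windows", {
  tt <- seq(0, 100, 0.5)
  cc <- 50 * exp(-0.05 * tt) + 5 * sin(tt / 7)^2
  a <- auc_trapz(tt, cc, 0, 37.5)
  b <- auc_trapz(tt, cc, 37.5, 100)
  expect_equal(a + b, auc_trapz(tt, cc, 0, 100), tolerance = 1e-10)
  # also with off-grid interior split
  a2 <- auc_trapz(tt, cc, 0, 37.2)
  b2 <- auc_trapz(tt, cc, 37.2, 100)
  expect_equal(a2 + b2, auc_trapz(tt, cc, 0, 100), tolerance = 1e-10)
})

test_that("peak picking reports the first grid maximum", {
  expect_equal(cmax_tmax(0:5, c(5, 4, 3, 2, 1, 0)),
               list(cmax = 5, tmax = 0))
  expect_equal(cmax_tmax(0:4, c(1, 7, 3, 7, 2)),
               list(cmax = 7, tmax = 1))
})

test_that("moment analysis recovers the volume of a one-compartment system", {
  # C(t) = D/V exp(-k t): Vss from Dose*AUMC/AUC^2 equals V for any k
  v <- 62.3; k <- 0.08; dose <- 5
  tt <- seq(0, 400, 0.01)
  cc <- 1000 * dose / v * exp(-k * tt)
  res <- structure(list(
    time_h = tt, plasma_conc_ng_ml = cc,
    regimen = regimen("iv_bolus", dose),
    model = list(individual = list(weight_kg = 70))
  ), class = "simulation_result")
  out <- vss_moment(res)
  expect_equal(out$vss_l, v, tolerance = 1e-3)
  expect_equal(out$cl_l_h, v * k, tolerance = 1e-3)
  expect_false(out$tail_flagged)
  # truncating early flags the extrapolated tail
  short <- res
  short$time_h <- tt[tt <= 5]
  short$plasma_conc_ng_ml <- cc[tt <= 5]
  expect_warning(vss_moment(short), "tail")
})

test_that("bioavailability is the dose-normalised AUC ratio", {
  expect_equal(f_abs(100, 100, 10, 10), 100)
  expect_equal(f_abs(0, 100, 10, 10), 0)
  expect_equal(f_abs(500, 697, 20, 2.97), 100 * (500 / 20) / (697 / 2.97))
  # invariant under dose scaling of a linear model
  expect_equal(f_abs(500, 697, 20, 2.97), f_abs(250, 697, 10, 2.97))
  expect_error(f_abs(100, 0, 10, 10), "positive")
})

test_that("troughs accumulate monotonically with shrinking increments", {
  md <- adult_sim("multi")
  tr <- troughs(md)
  expect_length(tr, 10)
  expect_true(all(diff(tr) > 0))
  expect_true(all(diff(diff(tr)) < 0))
  # a single dose decays to near nothing over many half-lives
  m <- build_model(reference_adult(), test_drug())
  one <- simulate_regimen(m, regimen("oral", 20), 480)
  tail_c <- stats::approx(one$time_h, one$plasma_conc_ng_ml, 480)$y
  expect_lt(tail_c, 0.02 * max(one$plasma_conc_ng_ml))
  expect_error(troughs(one, tau_h = 24, n_doses = 30), "span")
})
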