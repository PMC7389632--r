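test_that("zero residual noise returns the model predictions exactly", {
  drug <- test_drug()
  profs <- gen_observed(drug, regimen("oral", 20),
                        pop_spec = population_spec(2, 0, 29, 29, seed = 5),
                        sample_times_h = c(1, 6, 24, 48),
                        noise_cv = 0, seed = 9)
  for (p in profs) {
    expect_equal(p$conc_ng_ml, p$true_conc_ng_ml, tolerance = 1e-12)
  }
})

test_that("synthetic profiles are reproducible and seed-sensitive", {
  drug <- test_drug()
  args <- list(drug, regimen("oral", 20),
               pop_spec = population_spec(3, 0.5, 21, 37, seed = 5),
               sample_times_h = c(2, 6, 24), noise_cv = 0.2)
  a <- do.call(gen_observed, c(args, seed = 4))
  b <- do.call(gen_observed, c(args, seed = 4))
  c_ <- do.call(gen_observed, c(args, seed = 5))
  expect_identical(a, b)
  expect_false(identical(a, c_))
})

test_that("residual noise is multiplicative with geometric mean one", {
  drug <- test_drug()
  profs <- gen_observed(drug, regimen("oral", 20),
                        pop_spec = population_spec(12, 0, 21, 37, seed = 2),
                        noise_cv = 0.15, seed = 3)
  ratios <- unlist(lapply(profs, function(p) {
    ok <- p$true_conc_ng_ml > 0
    p$conc_ng_ml[ok] / p$true_conc_ng_ml[ok]
  }))
  # 144 draws at sdlog ~ 0.149: the geometric mean stands within ~3 SE
  expect_equal(exp(mean(log(ratios))), 1, tolerance = 0.04)
  expect_equal(sd(log(ratios)), sqrt(log(1 + 0.15^2)), tolerance = 0.25)
  expect_true(all(ratios > 0))
})
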