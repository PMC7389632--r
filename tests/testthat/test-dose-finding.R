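test_that("the color rules classify exposures per the rule table", {
  w <- reference_window()
  # everything inside both ranges -> green
  expect_equal(classify_dose(c(min = 50, mean = 80, max = 110),
                             c(min = 700, mean = 1200, max = 1700), w)$label,
               "green")
  # everything below both ranges -> out
  expect_equal(classify_dose(c(min = 5, mean = 10, max = 20),
                             c(min = 100, mean = 200, max = 400), w)$label,
               "out")
  # AUC min/mean in range, AUC max above, Cmax min below -> blue
  expect_equal(classify_dose(c(min = 20, mean = 90, max = 160),
                             c(min = 700, mean = 1500, max = 2500), w)$label,
               "blue")
  # only the minima fall in range -> yellow
  expect_equal(classify_dose(c(min = 50, mean = 150, max = 300),
                             c(min = 700, mean = 2500, max = 5000), w)$label,
               "yellow")
  # green takes precedence over the weaker labels
  expect_equal(classify_dose(c(min = 40, mean = 80, max = 120),
                             c(min = 650, mean = 1200, max = 1800), w)$label,
               "green")
})

test_that("dose grids follow the graded decremental design", {
  expect_equal(dose_grid("preschool"), c(20, 10, 5, 2.5, 1.5))
  expect_equal(dose_grid("neonates_to_infants"), c(5, 2.5, 1.5, 1))
  expect_error(dose_grid("toddlers"), "unknown group")
  # the stated percent reductions from the adult dose
  expect_equal(100 * (1 - dose_grid("school") / 20),
               c(0, 50, 75, 87.5, 92.5))
})

test_that("exposure falls monotonically over the descending grid", {
  d <- calibrated()$drug
  ds <- cached("search_school_small",
               decremental_search("school", d, n = 6, seed = 11))
  dec <- ds$decisions
  expect_true(all(diff(dec$auc_mean) < 0))
  expect_true(all(diff(dec$cmax_mean) < 0))
  # linear scaling means dose-normalised exposure is constant
  expect_equal(dec$auc_mean / dec$dose_mg,
               rep(dec$auc_mean[1] / dec$dose_mg[1], nrow(dec)),
               tolerance = 1e-12)
  # recommended range endpoints are grid members
  if (length(ds$recommended_range_mg)) {
    expect_true(all(ds$recommended_range_mg %in% dec$dose_mg))
  }
})

test_that("the adult population at 20 mg meets its own reference window", {
  d <- calibrated()$drug
  pop <- sample_population(population_spec(18, 0, 21, 37, seed = 1))
  ps <- cached("adult_pop_20mg",
               simulate_population(pop, d, reg = regimen("oral", 20),
                                   t_end_h = 120, rtol = 1e-6, atol = 1e-8))
  sub <- ps$subjects
  cl <- classify_dose(
    c(min = min(sub$cmax_ng_ml), mean = mean(sub$cmax_ng_ml),
      max = max(sub$cmax_ng_ml)),
    c(min = min(sub$auc_last_ng_h_ml), mean = mean(sub$auc_last_ng_h_ml),
      max = max(sub$auc_last_ng_h_ml)))
  expect_true(cl$label != "out")
})
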