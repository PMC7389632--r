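test_that("each rule equals the adult dose at the adult covariate", {
  expect_equal(clark_dose(150, 20), 20)
  expect_equal(weight_based_dose(70, 20, 70), 20)
  expect_equal(bsa_based_dose(1.73, 20, 1.73), 20)
  expect_equal(young_dose(1e9, 20), 20, tolerance = 1e-7)
  # strictly increasing in the covariate
  expect_true(all(diff(young_dose(1:17, 20)) > 0))
  expect_true(all(diff(clark_dose(seq(10, 150, 10), 20)) > 0))
  expect_error(young_dose(0), "positive")
  expect_error(clark_dose(-5), "positive")
})

test_that("unrounded doses match the closed forms", {
  expect_equal(young_dose(5, 20), 20 * 5 / 17, tolerance = 1e-12)
  expect_equal(clark_dose(22, 20), 22 / 150 * 20, tolerance = 1e-12)
  expect_equal(weight_based_dose(10, 20, 70), 2.857143, tolerance = 1e-6)
  expect_equal(bsa_based_dose(0.43, 20, 1.73), 4.9711, tolerance = 1e-4)
  # the published BSA column implies a larger adult BSA, which is exposed
  expect_equal(bsa_based_dose(0.43, 20, 1.82), 4.73, tolerance = 0.01)
})

test_that("the comparison table reproduces the printed dose columns", {
  tab <- comparison_table()
  expect_equal(tab$young_printed, c(1.53, 5.88, 10, 12))
  expect_equal(tab$clark_printed, c(2.93, 5, 12, 18))
  expect_equal(tab$weight_based_printed, c(2.85, 5, 11, 17))
  # same doses for both sexes by construction (no sex input), and the
  # PBPK range column is attached when provided
  tab2 <- comparison_table(pbpk_ranges = list(preschool = "1.5 to 5"))
  expect_equal(tab2$pbpk_range_mg[tab2$group == "preschool"], "1.5 to 5")
})

test_that("inconsistent dual weight units are rejected", {
  ch <- reference_children()
  ch$weight_lb <- ch$weight_kg * 2.20462 * 1.10
  expect_error(comparison_table(ch), "disagree")
})
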