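test_that("anthropometry hits the growth-table anchors and adult plateau", {
  expect_equal(anthropometry(1, "male")[["weight_kg"]], 10)
  expect_equal(anthropometry(5, "male")[["weight_kg"]], 17)
  expect_equal(anthropometry(29, "male")[["weight_kg"]], 70)
  expect_equal(anthropometry(29, "male")[["height_cm"]], 170)
  # interpolation is monotone in age
  ages <- seq(0.25, 20, by = 0.25)
  w <- vapply(ages, function(a) anthropometry(a, "female")[["weight_kg"]],
              numeric(1))
  expect_true(all(diff(w) >= 0))
  expect_error(anthropometry(0, "male"), "age")
})

test_that("pubertal sex offset applies between 12 and 18 years only", {
  a15 <- anthropometry(15, "male")[["weight_kg"]] /
    anthropometry(15, "female")[["weight_kg"]]
  expect_equal(a15, 1.03 / 0.97, tolerance = 1e-10)
  expect_equal(anthropometry(29, "male"), anthropometry(29, "female"))
  expect_equal(anthropometry(8, "male"), anthropometry(8, "female"))
})

test_that("Mosteller BSA matches hand-computed values and rejects bad input", {
  expect_equal(bsa(170, 70), sqrt(170 * 70 / 3600), tolerance = 1e-12)
  expect_equal(bsa(170, 70), 1.8181, tolerance = 1e-4)
  expect_equal(bsa(110, 17), 0.7207, tolerance = 1e-4)
  expect_error(bsa(170, 0), "positive")
})

test_that("GFR maturation is a monotone sigmoid exceeding 90% at age 1", {
  expect_equal(gfr_fraction(1), 0.9037, tolerance = 1e-4)
  expect_equal(gfr_fraction(0), 0.3547, tolerance = 1e-4)
  expect_gte(gfr_fraction(1), 0.90)
  ages <- seq(0, 30, by = 0.1)
  f <- gfr_fraction(ages)
  expect_true(all(diff(f) >= 0))
  expect_true(all(f > 0 & f <= 1))
  expect_equal(gfr_fraction(1e6), 1, tolerance = 1e-9)
  expect_error(gfr_fraction(-1), "non-negative")
})

test_that("built individuals satisfy the volume and flow invariants", {
  for (age in c(0.5, 1, 5, 12, 29)) {
    ind <- build_individual(age, "female")
    expect_true(all(ind$organ_volumes > 0))
    expect_true(all(ind$blood_flows > 0))
    expect_lt(abs(sum(ind$organ_volumes) - ind$weight_kg) / ind$weight_kg,
              0.15)
    expect_equal(sum(ind$blood_flows), ind$cardiac_output_l_h,
                 tolerance = 1e-9)
  }
  # every organ smaller in a 1-year-old than in an adult
  child <- build_individual(1, "male")
  adult <- build_individual(29, "male")
  expect_true(all(child$organ_volumes < adult$organ_volumes))
  # overrides are applied and unknown keys rejected
  ind <- build_individual(29, "male", overrides = list(weight_kg = 73))
  expect_equal(ind$weight_kg, 73)
  expect_error(build_individual(29, "male", overrides = list(wt = 73)),
               "unknown override")
})

test_that("population sampling is exact on the spec and reproducible", {
  spec <- population_spec(100, 0.5, 2, 5, seed = 42)
  pop <- sample_population(spec)
  df <- population_df(pop)
  expect_equal(sum(df$sex == "female"), 50)
  expect_true(all(df$age_years >= 2 & df$age_years <= 5))
  pop2 <- sample_population(spec)
  expect_identical(population_df(pop2), df)
  # odd female count rounds half up
  spec3 <- population_spec(3, 0.5, 2, 5, seed = 1)
  expect_equal(sum(population_df(sample_population(spec3))$sex == "female"), 2)
  # height CV close to nominal at larger n
  spec_h <- population_spec(400, 0, 29, 29, seed = 9)
  h <- population_df(sample_population(spec_h))$height_cm
  expect_equal(sd(h) / mean(h), 0.10, tolerance = 0.05)
})
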