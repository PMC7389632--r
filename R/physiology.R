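# Virtual individuals and populations: anthropometry, organ composition,
# blood flows, gut geometry and renal (GFR) maturation.

# Median growth table (unisex). Weight anchors follow the pediatric group
# values used throughout the dose comparison (10 kg at 1 y, 17 kg at 5 y,
# 40 kg at 12 y, 60 kg at 17 y) with an adult plateau of 70 kg / 170 cm.
.growth_table <- data.frame(
  age_years = c(0, 0.25, 0.5, 1, 2, 5, 8, 12, 15, 17, 20, 90),
  weight_kg = c(3.5, 6, 7.5, 10, 12.5, 17, 26, 40, 53, 60, 70, 70),
  height_cm = c(50, 60, 66, 75, 87, 110, 128, 150, 162, 166, 170, 170)
)

# Organ composition as fractions of body weight. Brain (in the richly
# perfused lump) and liver are relatively larger in infants; the poorly
# perfused lump absorbs the remainder so the total stays at 95% of weight.
.volume_fraction <- function(age_years) {
  total <- 0.95
  f <- c(
    venous_blood   = 0.040,
    arterial_blood = 0.020,
    lung           = 0.008,
    liver          = .age_taper(age_years, 0.035, 0.026),
    kidney         = .age_taper(age_years, 0.0070, 0.0044),
    gut_wall       = 0.017,
    rich           = .age_taper(age_years, 0.12, 0.05)
  )
  c(f, poor = total - sum(f))
}

# linear taper from the infant to the adult value over ages 0-15
.age_taper <- function(age, infant, adult) {
  w <- pmin(pmax(age / 15, 0), 1)
  infant * (1 - w) + adult * w
}

# Blood flows as fixed fractions of cardiac output (sum exactly 1).
.flow_fraction <- c(
  liver    = 0.065,
  kidney   = 0.190,
  gut_wall = 0.150,
  rich     = 0.350,
  poor     = 0.245
)

# Tissue water fractions used for partitioning of a hydrophilic,
# non-binding drug (Kp = kp_scalar * water fraction).
.tissue_water <- c(
  lung = 0.80, liver = 0.75, kidney = 0.78,
  gut_wall = 0.75, rich = 0.75, poor = 0.65
)

# Adult gut geometry (cm). Only length scales with height; radii follow a
# separate age table. Surface areas are smooth-cylinder values; mucosal
# amplification is absorbed into the calibrated effective permeability.
.gut_adult <- data.frame(
  segment   = c("stomach", "duodenum", "jejunum", "ileum", "colon"),
  length_cm = c(25, 25, 160, 120, 150),
  radius_cm = c(4.0, 1.6, 1.5, 1.25, 2.5),
  stringsAsFactors = FALSE
)

.gut_radius_age <- data.frame(
  age_years = c(0, 1, 5, 12, 17, 20, 90),
  scale     = c(0.35, 0.45, 0.60, 0.80, 0.95, 1.0, 1.0)
)

#' Median weight and height for an age
#'
#' Piecewise-linear interpolation over a built-in median growth table with an
#' adult plateau at 70 kg / 170 cm. A +/-3% sex offset (males
#' heavier/taller) is phased in between ages 12 and 14 and back out by 19,
#' reflecting the pubertal divergence; adults use the unisex reference
#' values.
#'
#' @param age_years Age in years, in (0, 90].
#' @param sex `"male"` or `"female"`.
#' @return Named numeric vector with `weight_kg` and `height_cm`.
#' @export
anthropometry <- function(age_years, sex = c("male", "female")) {
  sex <- match.arg(sex)
  if (!is.finite(age_years) || age_years <= 0 || age_years > 90) {
    stop("age_years must be in (0, 90]")
  }
  w <- stats::approx(.growth_table$age_years, .growth_table$weight_kg,
                     xout = age_years, rule = 2)$y
  h <- stats::approx(.growth_table$age_years, .growth_table$height_cm,
                     xout = age_years, rule = 2)$y
  # pubertal sex divergence: +/-3% at its widest, phased in over 12-14 y
  # and back out by 19 y so the unisex adult plateau is continuous
  ramp <- min(1, max(0, (age_years - 12) / 2)) *
    min(1, max(0, (19 - age_years) / 3))
  if (ramp > 0) {
    off <- 1 + (if (sex == "male") 0.03 else -0.03) * ramp
    w <- w * off
    h <- h * off
  }
  c(weight_kg = w, height_cm = h)
}

#' Body surface area (Mosteller)
#'
#' BSA (m^2) = sqrt(height_cm * weight_kg / 3600).
#'
#' @param height_cm Height in cm (> 0).
#' @param weight_kg Weight in kg (> 0).
#' @return BSA in m^2.
#' @export
bsa <- function(height_cm, weight_kg) {
  if (any(height_cm <= 0) || any(weight_kg <= 0)) {
    stop("height_cm and weight_kg must be positive")
  }
  sqrt(height_cm * weight_kg / 3600)
}

#' Renal maturation fraction
#'
#' Fraction of the size-normalised adult glomerular filtration rate reached
#' at a given age, modelled as a Hill sigmoid in postmenstrual age
#' (PMA = 40 + 52.14 * age weeks, hill 3.4, TM50 47.7 weeks). For a purely
#' renally cleared drug this reaches above 90% of the adult level by age
#' 1 year.
#'
#' @param age_years Postnatal age in years (>= 0, term birth).
#' @return Maturation fraction in (0, 1], non-decreasing in age.
#' @export
gfr_fraction <- function(age_years) {
  if (any(!is.finite(age_years)) || any(age_years < 0)) {
    stop("age_years must be non-negative")
  }
  pma <- 40 + 52.14 * age_years
  x <- (pma / 47.7)^3.4
  x / (1 + x)
}

#' Construct a virtual individual
#'
#' Builds the physiological parameter set for one subject: anthropometry,
#' lumped organ volumes (fraction-of-weight tables), blood flows as fixed
#' fractions of an allometric cardiac output (CO = 336 * (weight/70)^0.75
#' L/h), gut segment geometry (lengths proportional to height, radii from an
#' age table) and the GFR maturation fraction.
#'
#' @param age_years Age in years.
#' @param sex `"male"` or `"female"`.
#' @param overrides Optional named list overriding `weight_kg` and/or
#'   `height_cm` before derived quantities are computed.
#' @return An object of class `individual`.
#' @export
build_individual <- function(age_years, sex = c("male", "female"),
                             overrides = NULL) {
  sex <- match.arg(sex)
  anth <- anthropometry(age_years, sex)
  weight <- anth[["weight_kg"]]
  height <- anth[["height_cm"]]
  if (!is.null(overrides)) {
    allowed <- c("weight_kg", "height_cm")
    bad <- setdiff(names(overrides), allowed)
    if (length(bad)) {
      stop("unknown override keys: ", paste(bad, collapse = ", "))
    }
    if (!is.null(overrides$weight_kg)) weight <- overrides$weight_kg
    if (!is.null(overrides$height_cm)) height <- overrides$height_cm
  }

  vf <- .volume_fraction(age_years)
  organ_volumes <- vf * weight  # L (density ~ 1 kg/L)

  co <- 336 * (weight / 70)^0.75  # L/h
  blood_flows <- .flow_fraction * co

  rscale <- stats::approx(.gut_radius_age$age_years, .gut_radius_age$scale,
                          xout = age_years, rule = 2)$y
  gut <- .gut_adult
  gut$length_cm <- gut$length_cm * height / 170
  gut$radius_cm <- gut$radius_cm * rscale
  gut$surface_area_cm2 <- 2 * pi * gut$radius_cm * gut$length_cm
  gut$volume_ml <- pi * gut$radius_cm^2 * gut$length_cm

  structure(list(
    age_years = age_years,
    sex = sex,
    weight_kg = weight,
    height_cm = height,
    bsa_m2 = bsa(height, weight),
    organ_volumes = organ_volumes,
    blood_flows = blood_flows,
    cardiac_output_l_h = co,
    gut_geometry = gut,
    gfr_fraction = gfr_fraction(age_years)
  ), class = "individual")
}

#' @export
print.individual <- function(x, ...) {
  cat(sprintf(
    "<individual> %.2f y %s, %.1f kg, %.0f cm, BSA %.2f m2, GFR fraction %.3f\n",
    x$age_years, x$sex, x$weight_kg, x$height_cm, x$bsa_m2, x$gfr_fraction))
  invisible(x)
}

#' Population specification
#'
#' @param n Number of individuals (>= 1).
#' @param prop_female Proportion female in `[0, 1]`.
#' @param age_min_years,age_max_years Age bounds in years.
#' @param height_sd_fraction Coefficient of variation of the lognormal height
#'   multiplier (default 0.10, i.e. the +/-10% height standard deviation used
#'   for the virtual populations).
#' @param seed Integer RNG seed; the sampled population is fully reproducible.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(n, prop_female, age_min_years, age_max_years,
                            height_sd_fraction = 0.10, seed = 1L) {
  stopifnot(n >= 1, prop_female >= 0, prop_female <= 1,
            age_min_years <= age_max_years, height_sd_fraction >= 0)
  structure(list(
    n = as.integer(n), prop_female = prop_female,
    age_min_years = age_min_years, age_max_years = age_max_years,
    height_sd_fraction = height_sd_fraction, seed = as.integer(seed)
  ), class = "population_spec")
}

# Run code with a private, restored RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Sample a virtual population
#'
#' Draws `n` individuals: exactly `round(n * prop_female)` females (round half
#' up), ages uniform over the spec's range, heights multiplied by a lognormal
#' factor with the spec's CV, and weights co-varying with height through a
#' constant-BMI rule (weight scales with the squared height deviation from
#' the age/sex median).
#'
#' @param spec A [population_spec()].
#' @return List of `individual` objects.
#' @export
sample_population <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  n_f <- floor(spec$n * spec$prop_female + 0.5)
  sexes <- c(rep("female", n_f), rep("male", spec$n - n_f))
  cv <- spec$height_sd_fraction
  sdlog <- sqrt(log(1 + cv^2))
  with_seed(spec$seed, {
    ages <- stats::runif(spec$n, spec$age_min_years, spec$age_max_years)
    hmult <- exp(stats::rnorm(spec$n, -sdlog^2 / 2, sdlog))
    lapply(seq_len(spec$n), function(i) {
      anth <- anthropometry(ages[i], sexes[i])
      h <- anth[["height_cm"]] * hmult[i]
      w <- anth[["weight_kg"]] * (h / anth[["height_cm"]])^2
      build_individual(ages[i], sexes[i],
                       overrides = list(weight_kg = w, height_cm = h))
    })
  })
}

#' Demographics of a population as a data frame
#'
#' One row per individual with id, age, sex, weight, height, BSA and GFR
#' maturation fraction; suitable for CSV export.
#'
#' @param pop List of `individual` objects.
#' @return A data.frame.
#' @export
population_df <- function(pop) {
  data.frame(
    id = seq_along(pop),
    age_years = vapply(pop, `[[`, numeric(1), "age_years"),
    sex = vapply(pop, `[[`, character(1), "sex"),
    weight_kg = vapply(pop, `[[`, numeric(1), "weight_kg"),
    height_cm = vapply(pop, `[[`, numeric(1), "height_cm"),
    bsa_m2 = vapply(pop, `[[`, numeric(1), "bsa_m2"),
    gfr_fraction = vapply(pop, `[[`, numeric(1), "gfr_fraction"),
    stringsAsFactors = FALSE
  )
}
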