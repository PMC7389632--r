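# Conventional pediatric dose calculators and the comparison report.

#' Young's rule
#'
#' Pediatric dose = adult dose x age / (age + 12).
#'
#' @param age_years Child age, years (> 0).
#' @param adult_dose_mg Adult dose, mg (default 20).
#' @return Dose in mg (unrounded).
#' @export
young_dose <- function(age_years, adult_dose_mg = 20) {
  if (any(age_years <= 0)) stop("age_years must be positive")
  adult_dose_mg * age_years / (age_years + 12)
}

#' Clark's rule
#'
#' Pediatric dose = adult dose x weight(lb) / 150, i.e. the child's weight
#' as a percentage of a 150 lb adult applied to the adult dose.
#'
#' @param weight_lb Child weight, pounds (> 0).
#' @param adult_dose_mg Adult dose, mg.
#' @return Dose in mg (unrounded).
#' @export
clark_dose <- function(weight_lb, adult_dose_mg = 20) {
  if (any(weight_lb <= 0)) stop("weight_lb must be positive")
  adult_dose_mg * weight_lb / 150
}

#' Weight-based (mg/kg) dose
#'
#' Pediatric dose = adult dose x weight(kg) / adult weight(kg).
#'
#' @param weight_kg Child weight, kg (> 0).
#' @param adult_dose_mg Adult dose, mg.
#' @param adult_weight_kg Reference adult weight, kg (default 70).
#' @return Dose in mg (unrounded).
#' @export
weight_based_dose <- function(weight_kg, adult_dose_mg = 20,
                              adult_weight_kg = 70) {
  if (any(weight_kg <= 0) || adult_weight_kg <= 0) {
    stop("weights must be positive")
  }
  adult_dose_mg * weight_kg / adult_weight_kg
}

#' Body-surface-area-based dose
#'
#' Pediatric dose = adult dose x BSA / adult BSA. The reference adult BSA
#' defaults to the conventional 1.73 m^2; the published comparison table is
#' only reproduced with an adult BSA around 1.82-1.92 m^2, so the parameter
#' is exposed rather than guessed.
#'
#' @param bsa_m2 Child BSA, m^2 (> 0).
#' @param adult_dose_mg Adult dose, mg.
#' @param adult_bsa_m2 Reference adult BSA, m^2.
#' @return Dose in mg (unrounded).
#' @export
bsa_based_dose <- function(bsa_m2, adult_dose_mg = 20, adult_bsa_m2 = 1.73) {
  if (any(bsa_m2 <= 0) || adult_bsa_m2 <= 0) stop("BSA must be positive")
  adult_dose_mg * bsa_m2 / adult_bsa_m2
}

# Printed-precision formatter for the comparison table. The reference
# table's precision varies by column: values are truncated (not rounded)
# to 2 decimals below a column-specific threshold and rounded to whole
# milligrams at or above it (10 mg for Young's rule, 4 mg for Clark's and
# the weight-based rule).
.print_dose <- function(x, integer_from) {
  vapply(x, function(v) {
    if (is.finite(integer_from) && v >= integer_from) {
      round(v)
    } else {
      trunc(v * 100) / 100
    }
  }, numeric(1))
}

#' Conventional-dose comparison table
#'
#' Computes all four conventional doses for a set of child specifications
#' and formats them at the printed precision of the published comparison
#' (truncation to 2 decimals below a column-specific integer-rounding
#' threshold). Doses are the same for both
#' sexes. Optionally appends the PBPK-recommended dose range per group.
#'
#' @param children Data.frame with columns `group`, `age_years`,
#'   `weight_kg`, `bsa_m2` and optionally `weight_lb` (derived as
#'   kg x 2.20462 when absent).
#' @param adult_dose_mg Adult reference dose, mg.
#' @param adult_weight_kg,adult_bsa_m2 Adult reference covariates.
#' @param pbpk_ranges Optional named list/vector of strings, PBPK
#'   recommended range per group.
#' @return Data.frame: one row per child with raw and printed doses.
#' @export
comparison_table <- function(children = reference_children(),
                             adult_dose_mg = 20,
                             adult_weight_kg = 70, adult_bsa_m2 = 1.73,
                             pbpk_ranges = NULL) {
  ch <- children
  if (is.null(ch$weight_lb)) ch$weight_lb <- ch$weight_kg * 2.20462
  if (!is.null(ch$weight_kg) && !is.null(children$weight_lb)) {
    ratio <- ch$weight_lb / (ch$weight_kg * 2.20462)
    # tolerance accommodates tables printing both units rounded to
    # whole pounds/kilograms (e.g. 37 lb alongside 17 kg)
    if (any(abs(ratio - 1) > 0.03)) {
      stop("weight_lb and weight_kg disagree by more than 3%")
    }
  }
  young <- young_dose(ch$age_years, adult_dose_mg)
  clark <- clark_dose(ch$weight_lb, adult_dose_mg)
  wt <- weight_based_dose(ch$weight_kg, adult_dose_mg, adult_weight_kg)
  bs <- bsa_based_dose(ch$bsa_m2, adult_dose_mg, adult_bsa_m2)
  out <- data.frame(
    group = ch$group, age_years = ch$age_years,
    weight_lb = ch$weight_lb, weight_kg = ch$weight_kg, bsa_m2 = ch$bsa_m2,
    young_mg = young, clark_mg = clark, weight_based_mg = wt,
    bsa_based_mg = bs,
    young_printed = .print_dose(young, 10),
    clark_printed = .print_dose(clark, 4),
    weight_based_printed = .print_dose(wt, 4),
    bsa_based_printed = round(bs, 2),
    stringsAsFactors = FALSE
  )
  if (!is.null(pbpk_ranges)) {
    out$pbpk_range_mg <- vapply(as.character(out$group), function(g) {
      if (!is.null(pbpk_ranges[[g]])) as.character(pbpk_ranges[[g]]) else NA_character_
    }, character(1))
  }
  out
}

#' Reference children for the comparison table
#'
#' The four index children of the published comparison: ages 1, 5, 12 and
#' 17 years with weights 22/37/88/132 lb (10/17/40/60 kg) and BSA
#' 0.43/0.78/1.25/1.58 m^2. The BSA values are taken as given inputs (the
#' heights behind them are not published).
#'
#' @return Data.frame usable as `children` in [comparison_table()].
#' @export
reference_children <- function() {
  data.frame(
    group = c("infants_to_toddler", "preschool", "school", "adolescent"),
    age_years = c(1, 5, 12, 17),
    weight_lb = c(22, 37, 88, 132),
    weight_kg = c(10, 17, 40, 60),
    bsa_m2 = c(0.43, 0.78, 1.25, 1.58),
    stringsAsFactors = FALSE
  )
}
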