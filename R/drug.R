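# Lisinopril parameter set, tissue partitioning and oral release kinetics.

#' Drug parameter set
#'
#' Container for the physicochemical and kinetic parameters the PBPK model
#' consumes. The packaged defaults describe lisinopril: hydrophilic
#' (logP -1.22), a zwitterion (pKa 2.5, stored for documentation only),
#' freely soluble (97000 mg/L), no plasma protein binding, no metabolism,
#' purely renal elimination. The effective intestinal permeability, renal
#' clearance, partition scalar, fed-state delay and deep-distribution
#' exchange rates are calibrated quantities (see [calibrate_workflow()]);
#' their defaults are pre-calibration starting points.
#'
#' @param log_p Octanol-water log partition coefficient.
#' @param pka Acid dissociation constant (documentation only).
#' @param mw_g_mol Molecular weight, g/mol.
#' @param solubility_mg_l Aqueous solubility at reference pH, mg/L.
#' @param fu_plasma Unbound fraction in plasma, (0, 1].
#' @param peff_cm_min Effective intestinal permeability, cm/min (calibrated;
#'   an apparatus-internal literature reference point of 3.6e-7 cm/min exists
#'   but is on a different internal scale and is not a constraint).
#' @param cl_renal_adult_l_h Adult renal clearance, L/h (calibrated; the
#'   printed literature values, e.g. 2.82 L/h, only seed the search bracket).
#' @param kp_scalar Scalar multiplying tissue water fractions to give Kp.
#' @param deep_kin_per_h,deep_kout_per_h Linear exchange rates (1/h) between
#'   plasma and a deep distribution compartment approximating slow,
#'   high-affinity ACE binding.
#' @param fed_alpha Dimensionless fed-state gastric-emptying delay factor:
#'   emptying time is multiplied by `1 + fed_alpha * meal_kcal / 524`.
#' @param regional_perm_weights Named multipliers (0-1) on the permeability
#'   by gut segment, encoding the duodenum/jejunum-dominant absorptive
#'   transporter (PEPT1) expression pattern.
#' @return Object of class `drug_parameters`.
#' @export
drug_parameters <- function(log_p = -1.22,
                            pka = 2.5,
                            mw_g_mol = 405.48,
                            solubility_mg_l = 97000,
                            fu_plasma = 1.0,
                            peff_cm_min = 1e-3,
                            cl_renal_adult_l_h = 2.82,
                            kp_scalar = 0.5,
                            deep_kin_per_h = 0.2,
                            deep_kout_per_h = 0.02,
                            fed_alpha = 2,
                            regional_perm_weights = c(duodenum = 1, jejunum = 1,
                                                      ileum = 0.5, colon = 0.1)) {
  stopifnot(mw_g_mol > 0, solubility_mg_l > 0,
            fu_plasma > 0, fu_plasma <= 1,
            peff_cm_min >= 0, cl_renal_adult_l_h > 0,
            kp_scalar >= 0, deep_kin_per_h >= 0, deep_kout_per_h > 0,
            fed_alpha >= 0,
            all(regional_perm_weights >= 0), all(regional_perm_weights <= 1))
  structure(list(
    log_p = log_p, pka = pka, mw_g_mol = mw_g_mol,
    solubility_mg_l = solubility_mg_l, fu_plasma = fu_plasma,
    peff_cm_min = peff_cm_min, cl_renal_adult_l_h = cl_renal_adult_l_h,
    kp_scalar = kp_scalar,
    deep_kin_per_h = deep_kin_per_h, deep_kout_per_h = deep_kout_per_h,
    fed_alpha = fed_alpha,
    regional_perm_weights = regional_perm_weights
  ), class = "drug_parameters")
}

#' Packaged lisinopril parameter set
#'
#' The default drug parameterisation with the published physicochemistry.
#' Kinetic parameters are starting values; run [calibrate_workflow()] to
#' obtain the calibrated set.
#'
#' @param ... Overrides passed to [drug_parameters()].
#' @export
lisinopril <- function(...) drug_parameters(...)

#' Oral formulation
#'
#' First-order release reaching 80% of the dose at `t80_min` minutes
#' (the conventional 30-minute / 80% release point of an immediate-release
#' tablet). Dissolution is never rate-limiting for a drug this soluble, so a
#' single first-order release constant represents the tabulated release
#' profile adequately.
#'
#' @param t80_min Time to 80% release, minutes (> 0).
#' @return Object of class `formulation`.
#' @export
formulation <- function(t80_min = 30) {
  if (!is.finite(t80_min) || t80_min <= 0) stop("t80_min must be positive")
  structure(list(release_model = "first_order", t80_min = t80_min),
            class = "formulation")
}

#' First-order release rate constant from the 80% release time
#'
#' `k_rel = -log(0.2) / (t80_min / 60)` so that `1 - exp(-k_rel * t80)` is
#' exactly 0.8.
#'
#' @param t80_min Time to 80% release, minutes.
#' @return Release rate constant, 1/h.
#' @export
release_rate <- function(t80_min) {
  if (!is.finite(t80_min) || t80_min <= 0) stop("t80_min must be positive")
  -log(0.2) / (t80_min / 60)
}

#' Tissue-to-plasma partition coefficients
#'
#' For a hydrophilic, non-binding drug the tissue partition coefficient is
#' modelled as a common scalar times the tissue water fraction.
#'
#' @param drug A [drug_parameters()] object.
#' @param individual An `individual` (unused beyond validation; partitioning
#'   is composition-based and age-independent here).
#' @return Named vector of Kp values for lung, liver, kidney, gut wall and
#'   the richly and poorly perfused lumps.
#' @export
kp_map <- function(drug, individual = NULL) {
  stopifnot(inherits(drug, "drug_parameters"))
  drug$kp_scalar * .tissue_water
}

#' Solve the partition scalar for a target steady-state volume
#'
#' Closed-form linear solve: with blood volume `Vb`, tissue volumes `V_T`,
#' water fractions `w_T` and deep-compartment pool `(kin/kout) * Vb`, the
#' steady-state distribution volume referenced to venous plasma is
#' `Vss = Vb + s * sum(V_T w_T) + (kin/kout) * Vb`; the returned scalar `s`
#' matches `Vss` to the target exactly.
#'
#' @param target_vss_l_per_kg Target Vss, L/kg (the published 0.89 L/kg is
#'   the calibration anchor).
#' @param individual An `individual`.
#' @param deep_kin_per_h,deep_kout_per_h Deep-compartment exchange rates.
#' @return The partition scalar (> 0).
#' @export
solve_kp_scalar <- function(target_vss_l_per_kg, individual,
                            deep_kin_per_h = 0, deep_kout_per_h = 1) {
  stopifnot(inherits(individual, "individual"))
  v <- individual$organ_volumes
  vb <- v[["venous_blood"]] + v[["arterial_blood"]]
  tissues <- names(.tissue_water)
  denom <- sum(v[tissues] * .tissue_water[tissues])
  target_l <- target_vss_l_per_kg * individual$weight_kg
  deep <- (deep_kin_per_h / deep_kout_per_h) * vb
  s <- (target_l - vb - deep) / denom
  if (s < 0) {
    stop("infeasible target Vss: below blood plus deep compartment volume")
  }
  s
}
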