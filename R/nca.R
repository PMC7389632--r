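# Non-compartmental PK metrics from concentration-time profiles.

#' Trapezoidal AUC over a window
#'
#' Linear trapezoidal rule on the sampling grid. The window endpoints may
#' fall between grid points, in which case the profile is linearly
#' interpolated there (consistent with the trapezoid), but must lie inside
#' the grid. AUC is exactly additive over adjacent windows.
#'
#' @param times Strictly increasing sample times, h.
#' @param conc Concentrations, ng/ml.
#' @param t_start,t_end Window, h.
#' @return AUC in ng.h/ml.
#' @export
auc_trapz <- function(times, conc, t_start = times[1], t_end = times[length(times)]) {
  stopifnot(length(times) == length(conc), length(times) >= 2,
            all(diff(times) > 0))
  if (t_start < times[1] - 1e-12 || t_end > times[length(times)] + 1e-12 ||
      t_start > t_end) {
    stop("AUC window outside the sampling grid")
  }
  inside <- times > t_start & times < t_end
  tt <- c(t_start, times[inside], t_end)
  cc <- c(stats::approx(times, conc, xout = t_start)$y,
          conc[inside],
          stats::approx(times, conc, xout = t_end)$y)
  sum(diff(tt) * (cc[-1] + cc[-length(cc)]) / 2)
}

#' Peak concentration and its time
#'
#' Maximum of the profile and the grid time at which it occurs (first
#' occurrence on ties; no interpolation between grid points).
#'
#' @param times Sample times, h.
#' @param conc Concentrations, ng/ml.
#' @return List with `cmax` and `tmax`.
#' @export
cmax_tmax <- function(times, conc) {
  stopifnot(length(times) == length(conc), length(times) >= 1)
  i <- which.max(conc)
  list(cmax = conc[i], tmax = times[i])
}

#' Terminal slope by log-linear regression
#'
#' Fits log(conc) against time over the last `tail_frac` of the time span
#' (points with positive concentration only).
#'
#' @param times,conc Profile.
#' @param tail_frac Fraction of the time span used for the fit.
#' @return `lambda_z` in 1/h.
#' @export
lambda_z <- function(times, conc, tail_frac = 0.2) {
  t0 <- times[length(times)] - tail_frac * (times[length(times)] - times[1])
  sel <- times >= t0 & conc > 0
  if (sum(sel) < 3) stop("too few positive points in the terminal window")
  fit <- stats::lm.fit(cbind(1, times[sel]), log(conc[sel]))
  lz <- -fit$coefficients[2]
  if (!is.finite(lz) || lz <= 0) stop("non-positive terminal slope")
  unname(lz)
}

# AUC and AUMC to infinity with exponential tail extrapolation
.moments_inf <- function(times, conc) {
  lz <- lambda_z(times, conc)
  n <- length(times)
  c_last <- conc[n]; t_last <- times[n]
  auc_last <- auc_trapz(times, conc)
  aumc_last <- auc_trapz(times, conc * times)
  list(
    lambda_z = lz,
    auc_inf = auc_last + c_last / lz,
    aumc_inf = aumc_last + c_last * t_last / lz + c_last / lz^2,
    tail_frac_auc = (c_last / lz) / (auc_last + c_last / lz)
  )
}

#' Non-compartmental summary of a simulation
#'
#' @param result A `simulation_result`.
#' @param auc_window Window (h) for `auc_last` (0-120 h for the oral
#'   protocols, 0-72 h for the IV protocol of the reference studies).
#' @return List with `cmax_ng_ml`, `tmax_h`, `auc_last_ng_h_ml`,
#'   `auc_inf_ng_h_ml`, `lambda_z_per_h`.
#' @export
pk_summary <- function(result, auc_window = c(0, min(120, max(result$time_h)))) {
  stopifnot(inherits(result, "simulation_result"))
  ct <- cmax_tmax(result$time_h, result$plasma_conc_ng_ml)
  m <- .moments_inf(result$time_h, result$plasma_conc_ng_ml)
  list(
    cmax_ng_ml = ct$cmax,
    tmax_h = ct$tmax,
    auc_last_ng_h_ml = auc_trapz(result$time_h, result$plasma_conc_ng_ml,
                                 auc_window[1], auc_window[2]),
    auc_inf_ng_h_ml = m$auc_inf,
    lambda_z_per_h = m$lambda_z
  )
}

#' Trough concentrations under repeated dosing
#'
#' Concentration at `t = k * tau` (the instant before each next dose),
#' k = 1..n_doses, read off the output grid.
#'
#' @param result A `simulation_result` spanning `n_doses * tau_h`.
#' @param tau_h Dosing interval, h.
#' @param n_doses Number of doses.
#' @return Numeric vector of troughs, ng/ml.
#' @export
troughs <- function(result, tau_h = result$regimen$tau_h,
                    n_doses = result$regimen$n_doses) {
  stopifnot(inherits(result, "simulation_result"))
  tt <- tau_h * seq_len(n_doses)
  if (max(result$time_h) < max(tt) - 1e-9) {
    stop("simulation does not span n_doses * tau_h")
  }
  stats::approx(result$time_h, result$plasma_conc_ng_ml, xout = tt)$y
}

#' Absolute oral bioavailability
#'
#' F = 100 x (AUCinf_oral / dose_oral) / (AUCinf_iv / dose_iv).
#'
#' @param auc_inf_oral,auc_inf_iv AUC to infinity, ng.h/ml.
#' @param dose_oral_mg,dose_iv_mg Doses, mg.
#' @return Bioavailability in percent.
#' @export
f_abs <- function(auc_inf_oral, auc_inf_iv, dose_oral_mg, dose_iv_mg) {
  if (auc_inf_iv <= 0) stop("IV AUC must be positive")
  100 * (auc_inf_oral / dose_oral_mg) / (auc_inf_iv / dose_iv_mg)
}

#' Steady-state volume of distribution by moment analysis
#'
#' Vss = Dose x AUMC / AUC^2 from an IV bolus profile, with exponential
#' tail extrapolation of both moments. A warning flags profiles whose
#' extrapolated tail exceeds 20% of AUCinf.
#'
#' @param result A `simulation_result` of an IV bolus.
#' @param dose_mg Dose, mg (defaults to the simulated regimen's dose).
#' @return List with `vss_l`, `vss_l_per_kg`, `mrt_h`, `cl_l_h`,
#'   `tail_flagged`.
#' @export
vss_moment <- function(result, dose_mg = result$regimen$dose_mg) {
  stopifnot(inherits(result, "simulation_result"))
  m <- .moments_inf(result$time_h, result$plasma_conc_ng_ml)
  flagged <- m$tail_frac_auc > 0.2
  if (flagged) {
    warning("extrapolated tail exceeds 20% of AUCinf; Vss flagged")
  }
  # dose mg, AUC ng.h/ml = ug.h/L: CL = 1000*dose/AUC (L/h)
  cl <- 1000 * dose_mg / m$auc_inf
  mrt <- m$aumc_inf / m$auc_inf
  vss <- cl * mrt
  list(vss_l = vss,
       vss_l_per_kg = vss / result$model$individual$weight_kg,
       mrt_h = mrt, cl_l_h = cl, tail_flagged = flagged)
}
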