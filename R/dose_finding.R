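# Graded decremental dose search: simulate a descending dose grid per
# pediatric group and classify population exposure against the adult
# reference window.

#' Adult reference pharmacokinetic window
#'
#' The adult 20 mg exposure window used to judge pediatric doses:
#' Cmax 86 +/- 48 (range 38-124) ng/ml, Tmax 6.2 +/- 1.1 (range 5.1-7.3) h,
#' AUC(0-120) 1231 +/- 620 (range 611-1851) ng.h/ml. Tmax is carried as a
#' report column only; classification uses Cmax and AUC.
#'
#' @param cmax_range,tmax_range,auc_range Numeric length-2 ranges.
#' @return Object of class `reference_window`.
#' @export
reference_window <- function(cmax_range = c(38, 124),
                             tmax_range = c(5.1, 7.3),
                             auc_range = c(611, 1851)) {
  stopifnot(cmax_range[1] < cmax_range[2],
            tmax_range[1] < tmax_range[2],
            auc_range[1] < auc_range[2])
  structure(list(cmax_range = cmax_range, tmax_range = tmax_range,
                 auc_range = auc_range), class = "reference_window")
}

#' Pediatric group definitions
#'
#' The five pediatric age groups of the virtual-population study, each
#' simulated as 100 subjects, half female.
#'
#' @return Data.frame with `group`, `age_min_years`, `age_max_years`.
#' @export
pediatric_groups <- function() {
  data.frame(
    group = c("neonates_to_infants", "infants_to_toddler", "preschool",
              "school", "adolescent"),
    age_min_years = c(0.25, 1.0, 2.0, 5.0, 12.0),
    age_max_years = c(1.0, 2.0, 5.0, 12.0, 16.0),
    stringsAsFactors = FALSE
  )
}

#' Decremental dose grid for a pediatric group
#'
#' The graded decremental grids: 20, 10, 5, 2.5 and 1.5 mg (50, 75, 87.5
#' and 92.5% reductions from the 20 mg adult dose) for all groups except
#' neonates-to-infants, which uses 5, 2.5, 1.5 and 1 mg.
#'
#' @param group Group name (see [pediatric_groups()]).
#' @return Numeric vector of doses, mg, descending.
#' @export
dose_grid <- function(group) {
  groups <- pediatric_groups()$group
  if (!group %in% groups) {
    stop("unknown group: ", group, "; expected one of ",
         paste(groups, collapse = ", "))
  }
  if (group == "neonates_to_infants") c(5, 2.5, 1.5, 1) else c(20, 10, 5, 2.5, 1.5)
}

#' Classify a dose's population exposure against the reference window
#'
#' Applies the color rules used for the pediatric dose tables: considering
#' the population minimum, mean and maximum of Cmax and AUC(0-120),
#' a dose is `green` when all three statistics of both metrics fall in
#' range, `blue` when the AUC minimum and mean fall in range, `yellow`
#' when the minima of both metrics fall in range, and `out` otherwise
#' (precedence green > blue > yellow).
#'
#' @param cmax_stats,auc_stats Named numeric vectors with `min`, `mean`,
#'   `max` of the per-subject Cmax (ng/ml) and AUC (ng.h/ml).
#' @param window A [reference_window()].
#' @return List with per-metric in-range flags and the `label`.
#' @export
classify_dose <- function(cmax_stats, auc_stats, window = reference_window()) {
  inr <- function(x, r) x >= r[1] & x <= r[2]
  fc <- vapply(cmax_stats[c("min", "mean", "max")], inr,
               logical(1), window$cmax_range)
  fa <- vapply(auc_stats[c("min", "mean", "max")], inr,
               logical(1), window$auc_range)
  label <- if (all(fc) && all(fa)) "green"
           else if (fa[["min"]] && fa[["mean"]]) "blue"
           else if (fc[["min"]] && fa[["min"]]) "yellow"
           else "out"
  list(cmax_in = fc, auc_in = fa, label = label)
}

#' Graded decremental dose search for one pediatric group
#'
#' Simulates the group's virtual population once at a reference dose and
#' scales the per-subject exposure statistics across the dose grid (the
#' model is linear, so Cmax and AUC are exactly proportional to dose),
#' classifies every grid dose against the adult window, and reports the
#' recommended range as the lowest-to-highest grid dose whose label is not
#' `out`.
#'
#' @param group Group name.
#' @param drug Calibrated [drug_parameters()].
#' @param window A [reference_window()].
#' @param n Population size (100 in the study design).
#' @param seed RNG seed for the population draw.
#' @param form,transit Formulation and transit settings.
#' @param dt_out_h,rtol,atol Simulation settings.
#' @return Object of class `dose_search` with `decisions` (data.frame:
#'   dose, exposure statistics, label) and `recommended_range_mg`.
#' @export
decremental_search <- function(group, drug, window = reference_window(),
                               n = 100, seed = 1L,
                               form = formulation(),
                               transit = transit_times(),
                               dt_out_h = 0.05, rtol = 1e-6, atol = 1e-8) {
  grid <- dose_grid(group)
  g <- pediatric_groups()
  g <- g[g$group == group, ]
  spec <- population_spec(n = n, prop_female = 0.5,
                          age_min_years = g$age_min_years,
                          age_max_years = g$age_max_years, seed = seed)
  pop <- sample_population(spec)
  ref_dose <- max(grid)
  ps <- simulate_population(pop, drug, form,
                            regimen("oral", ref_dose), t_end_h = 120,
                            auc_window = c(0, 120), transit = transit,
                            dt_out_h = dt_out_h, rtol = rtol, atol = atol)
  sub <- ps$subjects
  rows <- lapply(grid, function(dose) {
    sc <- dose / ref_dose  # exact linear scaling of exposure
    cmax <- sub$cmax_ng_ml * sc
    auc <- sub$auc_last_ng_h_ml * sc
    cs <- c(min = min(cmax), mean = mean(cmax), max = max(cmax))
    as_ <- c(min = min(auc), mean = mean(auc), max = max(auc))
    cl <- classify_dose(cs, as_, window)
    data.frame(group = group, dose_mg = dose,
               cmax_min = cs[["min"]], cmax_mean = cs[["mean"]],
               cmax_max = cs[["max"]],
               auc_min = as_[["min"]], auc_mean = as_[["mean"]],
               auc_max = as_[["max"]],
               tmax_mean = mean(sub$tmax_h),
               label = cl$label, stringsAsFactors = FALSE)
  })
  decisions <- do.call(rbind, rows)
  ok <- decisions$dose_mg[decisions$label != "out"]
  structure(list(
    group = group,
    decisions = decisions,
    recommended_range_mg = if (length(ok)) range(ok) else numeric(0),
    population = ps
  ), class = "dose_search")
}

#' @export
print.dose_search <- function(x, ...) {
  cat("<dose_search>", x$group, "\n")
  print(x$decisions[, c("dose_mg", "cmax_mean", "auc_mean", "label")],
        row.names = FALSE)
  if (length(x$recommended_range_mg)) {
    cat(sprintf("recommended range: %.1f to %.1f mg\n",
                x$recommended_range_mg[1], x$recommended_range_mg[2]))
  } else {
    cat("no grid dose met the reference window\n")
  }
  invisible(x)
}

#' Run the dose search for every pediatric group
#'
#' @inheritParams decremental_search
#' @return Named list of `dose_search` objects, one per group.
#' @export
pediatric_dose_search <- function(drug, window = reference_window(),
                                  n = 100, seed = 1L, ...) {
  groups <- pediatric_groups()$group
  out <- lapply(groups, decremental_search, drug = drug, window = window,
                n = n, seed = seed, ...)
  stats::setNames(out, groups)
}
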