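# RE-AIM index engine: the eight components, the five indices (six values:
# maintenance has an individual and a setting arm), and the three composite
# impacts, using revised formulas that cannot go negative because every
# effect size they consume is bounded by 1 and differential effects enter as
# (1 - differential) multipliers rather than subtractions.

COMPONENT_NAMES <- c(
  "ipr", "dr", "icr_phase1", "outcome_phase1", "di_phase1",
  "spr", "cir", "icr_phase2", "outcome_phase2", "di_phase2", "scr"
)

#' Estimated eligible membership
#'
#' Applies prevalence rates to the insured adult membership: members are
#' eligible if obese, or overweight with at least one qualifying comorbid
#' condition, so the eligible count is
#' `n_adult_members * (p_obese + p_overweight * p_comorbid_overweight)`.
#'
#' @param model An [eligibility_model()].
#' @return The (possibly fractional) estimated eligible count.
#' @export
#' @examples
#' estimate_eligible(eligibility_model(60041, 0.31, 0.36, 0.66)) # 32878.45
estimate_eligible <- function(model) {
  model <- validate_eligibility_model(model)
  model$n_adult_members *
    (model$p_obese + model$p_overweight * model$p_comorbid_overweight)
}

#' Individual participation rate
#'
#' @param n_participants Number of enrollees (> 0).
#' @param n_eligible Eligible population size (> 0, may be fractional).
#' @return Proportion in \[0, 1\]; enrollment exceeding the eligible
#'   estimate warns and caps at 1.
#' @export
compute_ipr <- function(n_participants, n_eligible) {
  if (n_participants <= 0) abort("`n_participants` must be positive.")
  if (n_eligible <= 0) abort("`n_eligible` must be positive.")
  ipr <- n_participants / n_eligible
  if (ipr > 1) {
    warn("Participants exceed the eligible estimate; IPR capped at 1.")
    ipr <- 1
  }
  ipr
}

#' Aggregate differential effect sizes
#'
#' Unweighted arithmetic mean of the effect sizes measured across the
#' demographic dimensions examined (sex and age in the canonical analysis).
#'
#' @param effect_sizes Non-empty numeric vector with entries in \[0, 1\].
#' @return The mean, in \[0, 1\].
#' @export
#' @examples
#' aggregate_differential(c(0.073, 0.113)) # 0.093
aggregate_differential <- function(effect_sizes) {
  if (length(effect_sizes) == 0) abort("At least one effect size is required.")
  if (any(!is.finite(effect_sizes)) || any(effect_sizes < 0) ||
      any(effect_sizes > 1)) {
    abort("Effect sizes must lie in [0, 1].")
  }
  mean(effect_sizes)
}

check_unit <- function(x, name) {
  if (!is.finite(x) || x < 0 || x > 1) {
    abort(paste0("`", name, "` must lie in [0, 1]."))
  }
  x
}

#' Reach index
#'
#' `R = IPR * (1 - DR) * 100`: the participation rate discounted by how
#' unrepresentative enrollment is. Because DR is bounded by 1, the index
#' cannot go negative.
#'
#' @param ipr Individual participation rate in \[0, 1\].
#' @param dr Demographic-representativeness effect size in \[0, 1\].
#' @return Index value in \[0, 100\].
#' @export
#' @examples
#' compute_reach(0.059, 0.093) # 5.4 at one decimal
compute_reach <- function(ipr, dr) {
  check_unit(ipr, "ipr")
  check_unit(dr, "dr")
  ipr * (1 - dr) * 100
}

#' Effectiveness / individual-maintenance index
#'
#' `completion * outcome * (1 - differential) * 100`. With phase-I
#' components this is the effectiveness index E; with phase-II components
#' the identical formula gives the individual maintenance index M_I.
#'
#' @param icr Individual completion rate in \[0, 1\].
#' @param outcome Outcome effect size (partial eta squared) in \[0, 1\].
#' @param di Differential-impact effect size in \[0, 1\].
#' @return Index value in \[0, 100\].
#' @export
#' @examples
#' compute_effectiveness(0.765, 0.592, 0.032) # 43.8
#' compute_effectiveness(0.457, 0.467, 0.008) # 21.2 (individual maintenance)
compute_effectiveness <- function(icr, outcome, di) {
  check_unit(icr, "icr")
  check_unit(outcome, "outcome")
  check_unit(di, "di")
  icr * outcome * (1 - di) * 100
}

#' Simple rate index
#'
#' `(numerator / denominator) * 100`, serving adoption (sites running the
#' program over potential sites), implementation (mean components delivered
#' over the 14 in the protocol; the numerator may be fractional) and setting
#' maintenance (continuing sites over sites old enough to assess).
#'
#' @param numerator Non-negative number, at most `denominator`.
#' @param denominator Positive number.
#' @return Index value in \[0, 100\].
#' @export
#' @examples
#' compute_rate_index(31, 352)   # adoption 8.8
#' compute_rate_index(12.8, 14)  # implementation 91.4
#' compute_rate_index(14, 18)    # setting maintenance 77.8
compute_rate_index <- function(numerator, denominator) {
  if (denominator <= 0) abort("`denominator` must be positive.")
  if (numerator < 0 || numerator > denominator) {
    abort("`numerator` must lie in [0, denominator].")
  }
  numerator / denominator * 100
}

#' Composite impact values
#'
#' Individual-level impact = reach x effectiveness / 100, setting-level
#' impact = adoption x implementation / 100, long-term maintenance =
#' individual maintenance x setting maintenance / 100. By default the
#' factor indices are first rounded to one decimal — the precision at which
#' indices are reported — so printed impacts recompute exactly from printed
#' indices; set `round_indices = FALSE` for full-precision products.
#'
#' @param indices Named list or vector with `reach`, `effectiveness`,
#'   `adoption`, `implementation`, `maintenance_individual`,
#'   `maintenance_setting`, each in \[0, 100\].
#' @param round_indices Round factors to one decimal before multiplying.
#' @return Named numeric vector `impact_individual`, `impact_setting`,
#'   `impact_maintenance`, each in \[0, 100\].
#' @export
#' @examples
#' compute_impacts(list(reach = 5.4, effectiveness = 43.8, adoption = 8.8,
#'                      implementation = 91.4, maintenance_individual = 21.2,
#'                      maintenance_setting = 77.8))
compute_impacts <- function(indices, round_indices = TRUE) {
  need <- c("reach", "effectiveness", "adoption", "implementation",
            "maintenance_individual", "maintenance_setting")
  missing_idx <- setdiff(need, names(indices))
  if (length(missing_idx) > 0) {
    abort(paste0("Missing indices: ", paste(missing_idx, collapse = ", ")))
  }
  v <- vapply(indices[need], as.numeric, numeric(1))
  if (any(v < 0 | v > 100)) abort("Indices must lie in [0, 100].")
  if (round_indices) v <- round(v, 1)
  c(
    impact_individual = v[["reach"]] * v[["effectiveness"]] / 100,
    impact_setting = v[["adoption"]] * v[["implementation"]] / 100,
    impact_maintenance = v[["maintenance_individual"]] *
      v[["maintenance_setting"]] / 100
  )
}

#' Component values bundle
#'
#' Validated container for the eight operational components (eleven
#' values: the phase-specific completion, outcome and differential entries
#' are separate) feeding the index formulas.
#'
#' @param ipr,dr,icr_phase1,outcome_phase1,di_phase1,spr,cir,icr_phase2,outcome_phase2,di_phase2,scr
#'   Numbers in \[0, 1\].
#' @param n_eligible Positive number; the eligible-population denominator.
#' @return An object of class `component_values`.
#' @export
component_values <- function(ipr, dr, icr_phase1, outcome_phase1, di_phase1,
                             spr, cir, icr_phase2, outcome_phase2, di_phase2,
                             scr, n_eligible) {
  vals <- list(
    ipr = ipr, dr = dr, icr_phase1 = icr_phase1,
    outcome_phase1 = outcome_phase1, di_phase1 = di_phase1, spr = spr,
    cir = cir, icr_phase2 = icr_phase2, outcome_phase2 = outcome_phase2,
    di_phase2 = di_phase2, scr = scr
  )
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < 0 || v > 1) {
      abort(paste0("Component `", nm, "` must be a number in [0, 1]."))
    }
  }
  if (!is.finite(n_eligible) || n_eligible <= 0) {
    abort("`n_eligible` must be positive.")
  }
  structure(c(vals, list(n_eligible = n_eligible)),
            class = "component_values")
}

#' Derive all indices and impacts from component values
#'
#' @param components A [component_values()] bundle.
#' @param round_indices Passed to [compute_impacts()].
#' @return An object of class `reaim_indices`: named list of the six base
#'   indices and three impacts, all in \[0, 100\].
#' @export
compute_indices <- function(components, round_indices = TRUE) {
  stopifnot(inherits(components, "component_values"))
  idx <- list(
    reach = compute_reach(components$ipr, components$dr),
    effectiveness = compute_effectiveness(
      components$icr_phase1, components$outcome_phase1, components$di_phase1
    ),
    adoption = compute_rate_index(components$spr, 1),
    implementation = compute_rate_index(components$cir, 1),
    maintenance_individual = compute_effectiveness(
      components$icr_phase2, components$outcome_phase2, components$di_phase2
    ),
    maintenance_setting = compute_rate_index(components$scr, 1)
  )
  impacts <- compute_impacts(idx, round_indices = round_indices)
  structure(c(idx, as.list(impacts)), class = "reaim_indices")
}

#' @export
print.reaim_indices <- function(x, digits = 1, ...) {
  labels <- c(
    reach = "Reach (R)", effectiveness = "Effectiveness (E)",
    adoption = "Adoption (A)", implementation = "Implementation (I)",
    maintenance_individual = "Individual maintenance (M_I)",
    maintenance_setting = "Setting maintenance (M_S)",
    impact_individual = "Individual-level impact (R*E/100)",
    impact_setting = "Setting-level impact (A*I/100)",
    impact_maintenance = "Long-term maintenance (M_I*M_S/100)"
  )
  for (nm in names(labels)) {
    cat(sprintf("  %-36s %6.*f\n", labels[[nm]], digits, x[[nm]]))
  }
  invisible(x)
}

#' Legacy (pre-revision) index formulas
#'
#' The earlier calculation subtracted differential effects directly
#' (`reach = (IPR - DR) * 100`, `effectiveness = (ICR * O - DI) * 100`),
#' which can produce negative, hard-to-interpret index values whenever the
#' differential effect exceeds the positive term. Provided for comparison
#' with the revised formulas, which are non-negative by construction.
#'
#' @param components A [component_values()] bundle.
#' @return Named numeric vector of the legacy reach, effectiveness and
#'   individual-maintenance values (possibly negative).
#' @export
legacy_indices <- function(components) {
  stopifnot(inherits(components, "component_values"))
  c(
    reach = (components$ipr - components$dr) * 100,
    effectiveness = (components$icr_phase1 * components$outcome_phase1 -
                       components$di_phase1) * 100,
    maintenance_individual = (components$icr_phase2 *
                                components$outcome_phase2 -
                                components$di_phase2) * 100
  )
}

# ---- full pipeline -------------------------------------------------------

drop_small_groups <- function(g, min_size = 2) {
  g <- factor(g)
  small <- names(table(g))[table(g) < min_size]
  out <- as.character(g)
  out[out %in% small] <- NA
  factor(out)
}

compute_component_phase <- function(p, phase, data_collection_date,
                                    age_breaks) {
  w_end <- if (phase == 1) p$weight_lb_p1 else p$weight_lb_p2
  completed <- if (phase == 1) p$completed_phase1 else p$completed_phase2
  eligible <- phase_eligible(p$enrollment_date, phase, data_collection_date)
  if (!any(eligible)) {
    abort(paste0("No participants are phase-", phase, " eligible."))
  }
  icr <- mean(completed[eligible])

  comp <- completed & !is.na(p$weight_lb_baseline) & !is.na(w_end)
  fit_time <- rm_anova_two_timepoints(p$weight_lb_baseline[comp], w_end[comp])
  sex_fit <- rm_anova_two_timepoints(
    p$weight_lb_baseline[comp], w_end[comp], p$sex[comp]
  )
  age_groups <- drop_small_groups(
    assign_age_group(p$age_years[comp], age_breaks)
  )
  ok <- !is.na(age_groups)
  age_fit <- rm_anova_two_timepoints(
    p$weight_lb_baseline[comp][ok], w_end[comp][ok],
    droplevels(age_groups[ok])
  )
  list(
    icr = icr,
    outcome = fit_time$eta2_time,
    di = aggregate_differential(c(sex_fit$eta2_interaction,
                                  age_fit$eta2_interaction)),
    n_eligible = sum(eligible),
    n_completed = sum(completed[eligible])
  )
}

#' Evaluate a cohort: components, indices and impacts
#'
#' Runs the full evaluation pipeline over a cohort dataset: estimates the
#' eligible denominator from the eligibility model; computes the
#' participation rate; measures demographic representativeness (sex and
#' age) with [representativeness_phi2()]; computes phase-wise completion
#' rates among phase-eligible participants; fits the two-timepoint
#' repeated-measures model on weight for the outcome effect sizes, and
#' one-factor mixed models by sex and by age group for differential
#' impacts; derives the setting components from the site table (adoption
#' from active over potential sites, implementation from the mean count of
#' the 14 protocol components delivered, setting continuation among sites
#' approved at least a year before data collection); and feeds everything
#' through the revised index formulas.
#'
#' Any component may instead be supplied through `overrides` (e.g.
#' published effect sizes whose source tables are not part of the dataset);
#' the returned provenance log records, per component, whether it was
#' computed or supplied. With a complete override set `dataset` may be
#' `NULL`.
#'
#' @param dataset A `cohort_dataset`, or `NULL` when `overrides` supplies
#'   every component plus `n_eligible`.
#' @param overrides Named list of component values (names as in
#'   [component_values()]) to use in place of computation.
#' @param round_indices Passed to [compute_impacts()].
#' @return An object of class `reaim_evaluation`: list with `components`
#'   ([component_values()]), `indices` ([compute_indices()] output) and
#'   `provenance` (tibble: component, source, detail).
#' @export
reaim_evaluate <- function(dataset = NULL, overrides = NULL,
                           round_indices = TRUE) {
  overrides <- overrides %||% list()
  bad <- setdiff(names(overrides), c(COMPONENT_NAMES, "n_eligible"))
  if (length(bad) > 0) {
    abort(paste0("Unknown override component(s): ", paste(bad, collapse = ", ")))
  }
  vals <- list()
  prov <- list()
  want <- function(nm) !nm %in% names(overrides)
  note <- function(nm, source, detail) {
    prov[[nm]] <<- tibble(component = nm, source = source, detail = detail)
  }

  if (is.null(dataset)) {
    need <- c(COMPONENT_NAMES, "n_eligible")
    missing_ov <- setdiff(need, names(overrides))
    if (length(missing_ov) > 0) {
      abort(paste0(
        "Without a dataset, overrides must supply every component; missing: ",
        paste(missing_ov, collapse = ", ")
      ))
    }
  } else {
    stopifnot(inherits(dataset, "cohort_dataset"))
    p <- dataset$participants
    s <- dataset$sites
    dcd <- dataset$data_collection_date
    breaks <- dataset$age_breaks

    if (want("n_eligible")) {
      vals$n_eligible <- estimate_eligible(dataset$eligibility)
      note("n_eligible", "computed",
           sprintf("%d x (%.2f + %.2f x %.2f)",
                   dataset$eligibility$n_adult_members,
                   dataset$eligibility$p_obese,
                   dataset$eligibility$p_overweight,
                   dataset$eligibility$p_comorbid_overweight))
    }
    n_elig <- overrides$n_eligible %||% vals$n_eligible
    if (want("ipr")) {
      vals$ipr <- compute_ipr(nrow(p), n_elig)
      note("ipr", "computed", sprintf("%d / %.2f", nrow(p), n_elig))
    }
    if (want("dr")) {
      em <- dataset$eligibility
      sex_counts <- c(female = sum(p$sex == "female"),
                      male = sum(p$sex == "male"))
      sex_phi <- representativeness_phi2(
        sex_counts, c(em$eligible_sex_split, 1 - em$eligible_sex_split),
        round(n_elig)
      )
      age_counts <- table(assign_age_group(p$age_years, breaks))
      age_phi <- representativeness_phi2(
        as.numeric(age_counts), em$eligible_age_distribution, round(n_elig)
      )
      vals$dr <- aggregate_differential(c(sex_phi$phi_c2, age_phi$phi_c2))
      note("dr", "computed",
           sprintf("mean(sex phi_c2 = %.4f, age phi_c2 = %.4f); %s",
                   sex_phi$phi_c2, age_phi$phi_c2,
                   "participant-vs-nonparticipant convention"))
    }

    for (ph in 1:2) {
      icr_nm <- paste0("icr_phase", ph)
      out_nm <- paste0("outcome_phase", ph)
      di_nm <- paste0("di_phase", ph)
      if (want(icr_nm) || want(out_nm) || want(di_nm)) {
        cp <- compute_component_phase(p, ph, dcd, breaks)
        if (want(icr_nm)) {
          vals[[icr_nm]] <- cp$icr
          note(icr_nm, "computed",
               sprintf("%d / %d", cp$n_completed, cp$n_eligible))
        }
        if (want(out_nm)) {
          vals[[out_nm]] <- cp$outcome
          note(out_nm, "computed", "time eta2, weight baseline vs end-phase")
        }
        if (want(di_nm)) {
          vals[[di_nm]] <- cp$di
          note(di_nm, "computed",
               "mean of sex and age interaction eta2 (separate models)")
        }
      }
    }

    if (want("spr")) {
      vals$spr <- nrow(s) / dataset$n_potential_sites
      note("spr", "computed",
           sprintf("%d / %d", nrow(s), dataset$n_potential_sites))
    }
    if (want("cir")) {
      comp_cols <- sprintf("comp_%02d", 1:14)
      mean_comp <- mean(rowSums(as.matrix(s[, comp_cols]) * 1))
      vals$cir <- mean_comp / 14
      note("cir", "computed", sprintf("%.1f / 14", mean_comp))
    }
    if (want("scr")) {
      mature <- as.numeric(dcd - s$approval_date) >= 365
      if (!any(mature)) abort("No sites approved >= 1 year before collection.")
      vals$scr <- mean(s$still_accepting[mature])
      note("scr", "computed",
           sprintf("%d / %d", sum(s$still_accepting[mature]), sum(mature)))
    }
  }

  for (nm in names(overrides)) {
    vals[[nm]] <- overrides[[nm]]
    note(nm, "supplied", "override")
  }

  components <- do.call(component_values, vals[c(COMPONENT_NAMES, "n_eligible")])
  indices <- compute_indices(components, round_indices = round_indices)
  structure(
    list(
      components = components,
      indices = indices,
      provenance = dplyr::bind_rows(prov)
    ),
    class = "reaim_evaluation"
  )
}

#' @export
print.reaim_evaluation <- function(x, ...) {
  cat("RE-AIM evaluation\n")
  cat("Components (3 decimals):\n")
  for (nm in COMPONENT_NAMES) {
    src <- x$provenance$source[match(nm, x$provenance$component)]
    cat(sprintf("  %-16s %.3f  [%s]\n", nm, x$components[[nm]],
                src %||% "?"))
  }
  cat("Indices and impacts (1 decimal):\n")
  print(x$indices)
  invisible(x)
}
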