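# Cohort data model: participant and site tables, eligibility configuration,
# phase-eligibility and age-group classification.

SEX_LEVELS <- c("female", "male")
SITE_TYPES <- c("cardiac_rehab", "physical_therapy", "hospital", "fitness_center")

# Days a participant must have been enrolled before data collection to have
# had the chance to finish each phase: 12 weeks (phase I, the intervention)
# and 1 year (phase II, the maintenance benefit). Both boundaries inclusive.
PHASE_WINDOW_DAYS <- c(`1` = 84L, `2` = 365L)

DEFAULT_AGE_BREAKS <- c(18, 25, 35, 45, 55, 65)

#' Eligibility model for the insured population
#'
#' Describes the insured adult population from which the program draws:
#' total membership, the prevalence rates that define the eligible
#' denominator (obesity, overweight, and comorbidity among the overweight),
#' and the demographic composition of the eligible pool used for
#' representativeness comparisons.
#'
#' @param n_adult_members Positive integer; adult members covered.
#' @param p_obese Proportion of members who are obese (BMI >= 30).
#' @param p_overweight Proportion who are overweight (BMI 25-29.9).
#' @param p_comorbid_overweight Proportion of overweight members with at
#'   least one qualifying comorbid condition.
#' @param eligible_sex_split Proportion of the eligible pool who are female.
#' @param eligible_age_distribution Numeric vector of proportions over the
#'   age groups (see [assign_age_group()]), summing to 1.
#'
#' @return An object of class `eligibility_model`.
#' @export
#' @examples
#' em <- eligibility_model(60041, 0.31, 0.36, 0.66)
#' estimate_eligible(em)
eligibility_model <- function(n_adult_members,
                              p_obese,
                              p_overweight,
                              p_comorbid_overweight,
                              eligible_sex_split = 0.541,
                              eligible_age_distribution = c(
                                0.04, 0.13, 0.20, 0.24, 0.21, 0.18
                              )) {
  m <- structure(
    list(
      n_adult_members = n_adult_members,
      p_obese = p_obese,
      p_overweight = p_overweight,
      p_comorbid_overweight = p_comorbid_overweight,
      eligible_sex_split = eligible_sex_split,
      eligible_age_distribution = eligible_age_distribution
    ),
    class = "eligibility_model"
  )
  validate_eligibility_model(m)
}

#' @rdname eligibility_model
#' @param model An `eligibility_model` to validate.
#' @export
validate_eligibility_model <- function(model) {
  stopifnot(inherits(model, "eligibility_model"))
  if (!is.numeric(model$n_adult_members) || length(model$n_adult_members) != 1 ||
      model$n_adult_members <= 0 || model$n_adult_members %% 1 != 0) {
    abort("`n_adult_members` must be a positive integer.")
  }
  props <- c(
    model$p_obese, model$p_overweight, model$p_comorbid_overweight,
    model$eligible_sex_split, model$eligible_age_distribution
  )
  if (any(!is.finite(props)) || any(props < 0) || any(props > 1)) {
    abort("All eligibility proportions must lie in [0, 1].")
  }
  if (abs(sum(model$eligible_age_distribution) - 1) > 1e-9) {
    abort("`eligible_age_distribution` must sum to 1 (tolerance 1e-9).")
  }
  model
}

#' Assemble a cohort dataset
#'
#' Bundles participant records, site records, the data-collection date, the
#' eligibility model and the count of potential delivery sites into the
#' validated container consumed by the evaluation engine.
#'
#' @param participants Tibble of participant records (see [read_cohort()] for
#'   the column dictionary).
#' @param sites Tibble of site records.
#' @param eligibility An [eligibility_model()].
#' @param data_collection_date Date on which the database snapshot was taken.
#' @param n_potential_sites Positive integer; facilities in the state that
#'   could in principle deliver the program (the adoption denominator).
#' @param age_breaks Lower bounds of the age groups; see [assign_age_group()].
#' @param bmi_tolerance Allowed absolute discrepancy (kg/m^2) between a
#'   recorded BMI and 703 * weight / height^2 before a record is flagged.
#'
#' @return An object of class `cohort_dataset` with elements `participants`,
#'   `sites`, `eligibility`, `data_collection_date`, `n_potential_sites`,
#'   `age_breaks` and `flags` (tibble of non-fatal data-quality flags).
#' @export
cohort_dataset <- function(participants, sites, eligibility,
                           data_collection_date, n_potential_sites,
                           age_breaks = DEFAULT_AGE_BREAKS,
                           bmi_tolerance = 0.5) {
  ds <- structure(
    list(
      participants = as_tibble(participants),
      sites = as_tibble(sites),
      eligibility = validate_eligibility_model(eligibility),
      data_collection_date = as.Date(data_collection_date),
      n_potential_sites = n_potential_sites,
      age_breaks = age_breaks,
      flags = tibble(participant_id = character(), flag = character())
    ),
    class = "cohort_dataset"
  )
  validate_cohort(ds, bmi_tolerance = bmi_tolerance)
}

#' Validate a cohort dataset
#'
#' Enforces the structural invariants of the data model: ages at least 18,
#' phase-II completion implying phase-I completion, end-of-phase weight
#' present for completers, participant sites present in the site table,
#' enrollment no later than data collection, and exactly 14 implementation
#' components per site. BMI values inconsistent with `703 * weight_lb /
#' height_in^2` are flagged (not rejected): measurement protocols vary by
#' site, so disagreement is treated as a data-quality signal.
#'
#' @param ds A `cohort_dataset`.
#' @param bmi_tolerance Allowed BMI discrepancy before flagging.
#' @return The dataset, with `flags` populated.
#' @export
validate_cohort <- function(ds, bmi_tolerance = 0.5) {
  p <- ds$participants
  s <- ds$sites

  required_p <- c(
    "participant_id", "site_id", "sex", "age_years", "enrollment_date",
    "completed_phase1", "completed_phase2",
    "weight_lb_baseline", "weight_lb_p1", "weight_lb_p2", "height_in"
  )
  missing_cols <- setdiff(required_p, names(p))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "Participant table is missing columns: ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  comp_cols <- sprintf("comp_%02d", 1:14)
  required_s <- c("site_id", "site_type", "approval_date", comp_cols,
                  "still_accepting")
  missing_cols <- setdiff(required_s, names(s))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "Site table is missing columns: ", paste(missing_cols, collapse = ", ")
    ))
  }

  if (anyDuplicated(p$participant_id)) {
    dup <- unique(p$participant_id[duplicated(p$participant_id)])
    abort(paste0("Duplicate participant_id: ", paste(dup, collapse = ", ")))
  }
  bad_sex <- which(!p$sex %in% SEX_LEVELS)
  if (length(bad_sex) > 0) {
    abort(paste0(
      "Unknown sex code in participant rows: ",
      paste(utils::head(bad_sex, 10), collapse = ", ")
    ))
  }
  bad_type <- which(!s$site_type %in% SITE_TYPES)
  if (length(bad_type) > 0) {
    abort(paste0(
      "Unknown site_type code in site rows: ",
      paste(utils::head(bad_type, 10), collapse = ", ")
    ))
  }
  if (any(p$age_years < 18, na.rm = TRUE)) {
    abort("Participant ages below 18 are outside the program's domain.")
  }
  orphan <- setdiff(unique(p$site_id), s$site_id)
  if (length(orphan) > 0) {
    abort(paste0(
      "Participant site_id not present in site table: ",
      paste(orphan, collapse = ", ")
    ))
  }
  if (any(p$enrollment_date > ds$data_collection_date, na.rm = TRUE)) {
    abort("Enrollment dates after the data-collection date are invalid.")
  }
  if (any(p$completed_phase2 & !p$completed_phase1)) {
    abort("completed_phase2 implies completed_phase1; violations found.")
  }
  if (any(p$completed_phase1 & is.na(p$weight_lb_p1))) {
    abort("Phase-I completers must carry an end-of-phase-I weight.")
  }
  if (any(p$completed_phase2 & is.na(p$weight_lb_p2))) {
    abort("Phase-II completers must carry an end-of-phase-II weight.")
  }

  flags <- list()
  for (tp in c("baseline", "p1", "p2")) {
    bmi_col <- paste0("bmi_", tp)
    w_col <- paste0("weight_lb_", tp)
    if (!bmi_col %in% names(p)) next
    expect <- 703 * p[[w_col]] / p$height_in^2
    off <- which(!is.na(p[[bmi_col]]) & !is.na(expect) &
                   abs(p[[bmi_col]] - expect) > bmi_tolerance)
    if (length(off) > 0) {
      flags[[tp]] <- tibble(
        participant_id = p$participant_id[off],
        flag = paste0("bmi_inconsistent_", tp)
      )
    }
  }
  ds$flags <- dplyr::bind_rows(flags)
  if (nrow(ds$flags) > 0) {
    warn(paste0(
      nrow(ds$flags),
      " measurement(s) have BMI inconsistent with 703*weight/height^2",
      " beyond tolerance ", bmi_tolerance, "; records flagged, not dropped."
    ))
  }
  ds
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat("<cohort_dataset>\n")
  cat("  participants:", nrow(x$participants), "\n")
  cat("  sites:", nrow(x$sites), "of", x$n_potential_sites, "potential\n")
  cat("  data collection:", format(x$data_collection_date), "\n")
  cat("  flags:", nrow(x$flags), "\n")
  invisible(x)
}

#' Phase eligibility of a participant
#'
#' A participant can only be assessed for completion of a phase if enough
#' time elapsed between enrollment and the database snapshot: at least 84
#' days (12 weeks) for phase I and at least 365 days (1 year) for phase II.
#' Both boundaries are inclusive.
#'
#' @param enrollment_date Date vector of enrollment dates.
#' @param phase 1 or 2.
#' @param data_collection_date Snapshot date.
#' @return Logical vector.
#' @export
#' @examples
#' phase_eligible(as.Date("2007-10-01"), 1, as.Date("2007-12-24")) # 84 d
phase_eligible <- function(enrollment_date, phase, data_collection_date) {
  phase <- as.character(phase)
  if (!phase %in% c("1", "2")) abort("`phase` must be 1 or 2.")
  days <- as.numeric(as.Date(data_collection_date) - as.Date(enrollment_date))
  if (any(days < 0, na.rm = TRUE)) {
    abort("Enrollment after data collection; dates are inconsistent.")
  }
  days >= PHASE_WINDOW_DAYS[[phase]]
}

#' Age-group classification
#'
#' Bins adult ages into half-open ten-year groups starting at 18:
#' `[18,25)`, `[25,35)`, ..., `[55,65)`, `[65,Inf)` by default, so that an
#' age of 54.9 falls in `[45,55)` and 65.0 in `[65,Inf)`. The breaks are
#' configurable; the last group is always open-ended.
#'
#' @param age_years Numeric vector of ages (>= first break).
#' @param breaks Increasing numeric vector of lower bounds.
#' @return Factor with one level per group, in age order.
#' @export
#' @examples
#' assign_age_group(c(54.9, 65, 25))
assign_age_group <- function(age_years, breaks = DEFAULT_AGE_BREAKS) {
  if (is.unsorted(breaks, strictly = TRUE)) {
    abort("`breaks` must be strictly increasing.")
  }
  if (any(age_years < breaks[1], na.rm = TRUE)) {
    abort(paste0("Ages below ", breaks[1], " are outside the domain."))
  }
  labs <- age_group_labels(breaks)
  cut(age_years, breaks = c(breaks, Inf), right = FALSE, labels = labs)
}

age_group_labels <- function(breaks = DEFAULT_AGE_BREAKS) {
  upper <- c(breaks[-1], Inf)
  sprintf("[%g,%s)", breaks, vapply(upper, function(u) {
    if (is.finite(u)) sprintf("%g", u) else "Inf"
  }, character(1)))
}
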