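# Delimited-file input/output for cohort data.
#
# Column dictionary (participants.csv):
#   participant_id, site_id, sex {female,male}, age_years,
#   enrollment_date (ISO-8601), height_in,
#   weight_lb_baseline, weight_lb_p1, weight_lb_p2,
#   bmi_baseline, bmi_p1, bmi_p2,
#   sbp_baseline, sbp_p1, sbp_p2, dbp_baseline, dbp_p1, dbp_p2,
#   bodyfat_baseline, bodyfat_p1, bodyfat_p2,
#   waist_baseline, waist_p1, waist_p2,
#   completed_phase1, completed_phase2 (TRUE/FALSE)
# Sites file (sites.csv):
#   site_id, site_type {cardiac_rehab,physical_therapy,hospital,
#   fitness_center}, approval_date (ISO-8601), comp_01..comp_14 (0/1),
#   still_accepting (TRUE/FALSE)

MEASURE_STEMS <- c("weight_lb", "bmi", "sbp", "dbp", "bodyfat", "waist")
TIMEPOINTS <- c("baseline", "p1", "p2")

participant_measure_cols <- function() {
  as.vector(outer(MEASURE_STEMS, TIMEPOINTS, paste, sep = "_"))
}

participant_col_types <- function() {
  meas <- participant_measure_cols()
  types <- c(
    participant_id = "c", site_id = "c", sex = "c", age_years = "d",
    enrollment_date = "D", height_in = "d",
    setNames(rep("d", length(meas)), meas),
    completed_phase1 = "l", completed_phase2 = "l"
  )
  do.call(readr::cols_only, as.list(types))
}

site_col_types <- function() {
  types <- c(
    site_id = "c", site_type = "c", approval_date = "D",
    setNames(rep("l", 14), sprintf("comp_%02d", 1:14)),
    still_accepting = "l"
  )
  do.call(readr::cols_only, as.list(types))
}

read_checked <- function(path, col_types, what) {
  if (!file.exists(path)) {
    abort(paste0("Cannot read ", what, " file: ", path, " does not exist."))
  }
  x <- readr::read_csv(path, col_types = col_types, na = c("", "NA"),
                       progress = FALSE)
  probs <- readr::problems(x)
  if (nrow(probs) > 0) {
    abort(paste0(
    what, " file ", path, " has ", nrow(probs),
      " cell(s) that failed type coercion; first offending rows: ",
      paste(utils::head(unique(probs$row), 10), collapse = ", ")
    ))
  }
  x
}

#' Read a cohort from delimited files
#'
#' Loads the participant and site tables from CSV, validates them against
#' the documented column dictionary, and returns a checked
#' [cohort_dataset()]. Blank measurement cells load as missing values, never
#' as zero; rows that fail type coercion or carry unknown category codes are
#' reported with their row numbers.
#'
#' @param participants_path Path to the participant CSV.
#' @param sites_path Path to the site CSV.
#' @param config Either a list or a path to a JSON/YAML file providing
#'   `n_adult_members`, `p_obese`, `p_overweight`, `p_comorbid_overweight`,
#'   `eligible_sex_split`, `eligible_age_distribution`,
#'   `data_collection_date`, `n_potential_sites`, and optionally
#'   `age_breaks` and `bmi_tolerance`.
#' @return A validated `cohort_dataset`.
#' @export
read_cohort <- function(participants_path, sites_path, config) {
  cfg <- load_config(config)
  need <- c("n_adult_members", "p_obese", "p_overweight",
            "p_comorbid_overweight", "data_collection_date",
            "n_potential_sites")
  missing_keys <- setdiff(need, names(cfg))
  if (length(missing_keys) > 0) {
    abort(paste0("Config is missing: ", paste(missing_keys, collapse = ", ")))
  }

  p <- read_checked(participants_path, participant_col_types(), "participant")
  s <- read_checked(sites_path, site_col_types(), "site")

  bad_sex <- which(!p$sex %in% SEX_LEVELS)
  if (length(bad_sex) > 0) {
    abort(paste0(
      "Unknown sex code ", paste(unique(p$sex[bad_sex]), collapse = "/"),
      " in participant rows: ",
      paste(utils::head(bad_sex, 10), collapse = ", ")
    ))
  }

  em <- eligibility_model(
    n_adult_members = cfg$n_adult_members,
    p_obese = cfg$p_obese,
    p_overweight = cfg$p_overweight,
    p_comorbid_overweight = cfg$p_comorbid_overweight,
    eligible_sex_split = cfg$eligible_sex_split %||% 0.541,
    eligible_age_distribution = unlist(
      cfg$eligible_age_distribution %||% c(0.04, 0.13, 0.20, 0.24, 0.21, 0.18)
    )
  )
  cohort_dataset(
    participants = p,
    sites = s,
    eligibility = em,
    data_collection_date = as.Date(cfg$data_collection_date),
    n_potential_sites = cfg$n_potential_sites,
    age_breaks = unlist(cfg$age_breaks %||% DEFAULT_AGE_BREAKS),
    bmi_tolerance = cfg$bmi_tolerance %||% 0.5
  )
}

load_config <- function(config) {
  if (is.list(config)) return(config)
  if (!file.exists(config)) {
    abort(paste0("Config file does not exist: ", config))
  }
  ext <- tolower(tools::file_ext(config))
  if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      abort("Reading YAML configs requires the 'yaml' package.")
    }
    yaml::read_yaml(config)
  } else {
    jsonlite::read_json(config, simplifyVector = TRUE)
  }
}

#' Write a cohort to delimited files
#'
#' Emits `participants.csv`, `sites.csv`, `config.json` and a
#' `provenance.json` sidecar (seed and configuration hash when the cohort
#' was simulated) in the exact dialect [read_cohort()] consumes. Missing
#' values are written as empty cells.
#'
#' @param ds A `cohort_dataset`.
#' @param dir Output directory (created if needed).
#' @param provenance Optional named list recorded alongside the data (the
#'   simulator supplies `seed` and `config_hash`).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(ds, dir, provenance = NULL) {
  stopifnot(inherits(ds, "cohort_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pp <- file.path(dir, "participants.csv")
  sp <- file.path(dir, "sites.csv")
  cp <- file.path(dir, "config.json")
  keep <- c("participant_id", "site_id", "sex", "age_years",
            "enrollment_date", "height_in", participant_measure_cols(),
            "completed_phase1", "completed_phase2")
  readr::write_csv(ds$participants[, intersect(keep, names(ds$participants))],
                   pp, na = "")
  readr::write_csv(ds$sites, sp, na = "")
  cfg <- c(
    unclass(ds$eligibility),
    list(
      data_collection_date = format(ds$data_collection_date),
      n_potential_sites = ds$n_potential_sites,
      age_breaks = ds$age_breaks
    )
  )
  jsonlite::write_json(cfg, cp, auto_unbox = TRUE, digits = NA)
  paths <- c(participants = pp, sites = sp, config = cp)
  if (!is.null(provenance)) {
    vp <- file.path(dir, "provenance.json")
    jsonlite::write_json(provenance, vp, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, provenance = vp)
  }
  invisible(paths)
}
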