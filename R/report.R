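# Report assembly: component/index table, per-sex per-phase descriptive
# outcome tables with change-from-baseline columns, and completion tables.

COMPONENT_LABELS <- c(
  ipr = "Individual participation rate (IPR)",
  dr = "Demographic representativeness (DR)",
  icr_phase1 = "Phase I individual completion rate (ICR_PhI)",
  outcome_phase1 = "Phase I outcome (O_PhI)",
  di_phase1 = "Phase I differential impact (DI_PhI)",
  spr = "Setting participation rate (SPR)",
  cir = "Component implementation rate (CIR)",
  icr_phase2 = "Phase II individual completion rate (ICR_PhII)",
  outcome_phase2 = "Phase II outcome (O_PhII)",
  di_phase2 = "Phase II differential impact (DI_PhII)",
  scr = "Setting continuation rate (SCR)"
)

INDEX_LABELS <- c(
  reach = "Reach (R)",
  effectiveness = "Effectiveness (E)",
  adoption = "Adoption (A)",
  implementation = "Implementation (I)",
  maintenance_individual = "Individual maintenance (M_I)",
  maintenance_setting = "Setting maintenance (M_S)",
  impact_individual = "Individual-level impact (R*E/100)",
  impact_setting = "Setting-level impact (A*I/100)",
  impact_maintenance = "Long-term maintenance (M_I*M_S/100)"
)

REPORT_MEASURES <- c(
  weight_lb = "Weight, lb", weight_pct = "Weight, %",
  bmi = "BMI, kg/m2", sbp = "Systolic blood pressure, mm Hg",
  dbp = "Diastolic blood pressure, mm Hg", bodyfat = "Body fat, %",
  waist = "Waist, in"
)

summ_or_na <- function(values, digits = 1) {
  values <- values[!is.na(values)]
  if (length(values) < 2) {
    list(n = length(values), text = "NA")
  } else {
    s <- summarize_measure(values)
    list(n = s$n, text = format(s, digits = digits))
  }
}

descriptive_phase_table <- function(p, phase) {
  end_sfx <- paste0("_p", phase)
  completed <- if (phase == 1) p$completed_phase1 else p$completed_phase2
  rows <- list()
  for (sx in SEX_LEVELS) {
    sub <- p[completed & p$sex == sx, ]
    for (ms in names(REPORT_MEASURES)) {
      if (ms == "weight_pct") {
        # percent-of-baseline change computed per participant, then summarized
        end_v <- rep(NA_real_, nrow(sub))
        chg_v <- (sub[[paste0("weight_lb", end_sfx)]] -
                    sub$weight_lb_baseline) / sub$weight_lb_baseline * 100
      } else {
        end_v <- sub[[paste0(ms, end_sfx)]]
        chg_v <- end_v - sub[[paste0(ms, "_baseline")]]
      }
      se <- summ_or_na(end_v)
      sc <- summ_or_na(chg_v)
      rows[[paste(sx, ms)]] <- tibble(
        sex = sx, measurement = REPORT_MEASURES[[ms]],
        n_end = se$n, end_summary = se$text,
        n_change = sc$n, change_summary = sc$text
      )
    }
  }
  dplyr::bind_rows(rows)
}

completion_phase_table <- function(p, phase, data_collection_date,
                                   age_breaks) {
  eligible <- phase_eligible(p$enrollment_date, phase, data_collection_date)
  completed <- if (phase == 1) p$completed_phase1 else p$completed_phase2
  sub <- tibble(
    sex = p$sex[eligible],
    age_group = assign_age_group(p$age_years[eligible], age_breaks),
    completed = completed[eligible]
  )
  by_cell <- sub |>
    dplyr::group_by(.data$sex, .data$age_group) |>
    dplyr::summarise(
      n_eligible = dplyr::n(),
      n_completed = sum(.data$completed),
      rate = mean(.data$completed),
      .groups = "drop"
    )
  overall <- tibble(
    sex = "all", age_group = factor("all"),
    n_eligible = nrow(sub),
    n_completed = sum(sub$completed),
    rate = mean(sub$completed)
  )
  dplyr::bind_rows(by_cell, overall)
}

#' Build a full evaluation report
#'
#' Assembles the component/index table, the per-sex per-phase descriptive
#' outcome tables (end-of-phase values and change from baseline, where
#' negative change indicates improvement), the per-sex per-age-group
#' completion tables, and a provenance block. Components print at three
#' decimals and indices at one; measurements print as median (IQR) or mean
#' (SD) according to their skewness (see [summarize_measure()]); cells with
#' fewer than two observations render as `NA`.
#'
#' @param dataset A `cohort_dataset`, or `NULL` for an override-only
#'   evaluation (descriptive and completion tables are then empty).
#' @param evaluation A `reaim_evaluation` from [reaim_evaluate()].
#' @return An object of class `evaluation_report` with elements
#'   `component_table`, `index_table`, `descriptive_tables`,
#'   `completion_tables`, `provenance`.
#' @export
build_report <- function(dataset, evaluation) {
  stopifnot(inherits(evaluation, "reaim_evaluation"))
  comp <- evaluation$components
  formula_for <- function(nm) {
    detail <- evaluation$provenance$detail[
      match(nm, evaluation$provenance$component)
    ]
    src <- evaluation$provenance$source[
      match(nm, evaluation$provenance$component)
    ]
    if (isTRUE(src == "supplied")) "supplied" else detail %||% ""
  }
  component_table <- tibble(
    component = unname(COMPONENT_LABELS[COMPONENT_NAMES]),
    key = COMPONENT_NAMES,
    formula = unname(vapply(COMPONENT_NAMES, formula_for, character(1))),
    value = round(unname(vapply(COMPONENT_NAMES, function(nm) comp[[nm]],
                                numeric(1))), 3)
  )
  index_table <- tibble(
    index = unname(INDEX_LABELS[names(INDEX_LABELS)]),
    key = names(INDEX_LABELS),
    value = round(unname(vapply(names(INDEX_LABELS),
                                function(nm) evaluation$indices[[nm]],
                                numeric(1))), 1)
  )

  if (!is.null(dataset)) {
    p <- dataset$participants
    descriptive_tables <- list(
      phase1 = descriptive_phase_table(p, 1),
      phase2 = descriptive_phase_table(p, 2)
    )
    completion_tables <- list(
      phase1 = completion_phase_table(p, 1, dataset$data_collection_date,
                                      dataset$age_breaks),
      phase2 = completion_phase_table(p, 2, dataset$data_collection_date,
                                      dataset$age_breaks)
    )
    prov_ds <- attr(dataset, "provenance")
  } else {
    descriptive_tables <- list()
    completion_tables <- list()
    prov_ds <- NULL
  }

  structure(
    list(
      component_table = component_table,
      index_table = index_table,
      descriptive_tables = descriptive_tables,
      completion_tables = completion_tables,
      provenance = list(
        components = evaluation$provenance,
        dataset = prov_ds,
        software_version = as.character(utils::packageVersion("reaim"))
      )
    ),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("== RE-AIM component and index values ==\n")
  for (i in seq_len(nrow(x$component_table))) {
    cat(sprintf("  %-46s %6.3f  %s\n",
                x$component_table$component[i],
                x$component_table$value[i],
                x$component_table$formula[i]))
  }
  cat("\n")
  for (i in seq_len(nrow(x$index_table))) {
    cat(sprintf("  %-40s %6.1f\n", x$index_table$index[i],
                x$index_table$value[i]))
  }
  for (ph in names(x$completion_tables)) {
    ct <- x$completion_tables[[ph]]
    cat("\n== Completion, ", ph, " ==\n", sep = "")
    for (i in seq_len(nrow(ct))) {
      cat(sprintf("  %-7s %-10s %5d / %5d  (%.1f%%)\n",
                  ct$sex[i], as.character(ct$age_group[i]),
                  ct$n_completed[i], ct$n_eligible[i], 100 * ct$rate[i]))
    }
  }
  for (ph in names(x$descriptive_tables)) {
    dt <- x$descriptive_tables[[ph]]
    cat("\n== Outcomes, ", ph, " (end value; change from baseline) ==\n",
        sep = "")
    for (i in seq_len(nrow(dt))) {
      cat(sprintf("  %-7s %-32s n=%-5d %-22s n=%-5d %s\n",
                  dt$sex[i], dt$measurement[i], dt$n_end[i],
                  dt$end_summary[i], dt$n_change[i], dt$change_summary[i]))
    }
  }
  invisible(x)
}

#' Serialize a report to JSON
#'
#' Writes the report with the same numbers the text rendering shows
#' (components at three decimals, indices at one).
#'
#' @param report An `evaluation_report`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
report_to_json <- function(report, path) {
  stopifnot(inherits(report, "evaluation_report"))
  payload <- list(
    components = report$component_table,
    indices = report$index_table,
    completion = report$completion_tables,
    descriptives = report$descriptive_tables,
    provenance = report$provenance
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
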