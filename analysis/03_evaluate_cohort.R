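#!/usr/bin/env Rscript
# Step 3: read the simulated cohort back from its CSV form and run the full
# evaluation pipeline on it — every component computed from the data, no
# overrides — then write the index, completion and descriptive tables.
# Run analysis/02_simulate_cohort.R first.

suppressPackageStartupMessages({
  library(reaim)
  library(readr)
})

if (!file.exists("scratch/cohort/participants.csv")) {
  stop("No simulated cohort found; run analysis/02_simulate_cohort.R first.")
}

ds <- read_cohort("scratch/cohort/participants.csv",
                  "scratch/cohort/sites.csv",
                  "scratch/cohort/config.json")
ev <- reaim_evaluate(ds)
rep <- build_report(ds, ev)
print(rep)

dir.create("results", showWarnings = FALSE)
write_csv(rep$component_table, "results/synthetic_component_table.csv")
write_csv(rep$index_table, "results/synthetic_index_table.csv")
write_csv(rep$completion_tables$phase1, "results/synthetic_completion_phase1.csv")
write_csv(rep$completion_tables$phase2, "results/synthetic_completion_phase2.csv")
write_csv(rep$descriptive_tables$phase1, "results/synthetic_outcomes_phase1.csv")
write_csv(rep$descriptive_tables$phase2, "results/synthetic_outcomes_phase2.csv")
report_to_json(rep, "results/synthetic_report.json")

cat("\nData-driven components differ from the published ones exactly where\n")
cat("the underlying quantity is not identified by printed marginals alone\n")
cat("(demographic representativeness and the outcome effect sizes); the\n")
cat("completion-, site- and participation-rate components track their\n")
cat("calibration targets. Tables written under results/.\n")
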