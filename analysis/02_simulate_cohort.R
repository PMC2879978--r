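#!/usr/bin/env Rscript
# Step 2: draw a synthetic cohort under the calibrated study conditions
# (1,952 enrollees, 31 of 352 sites, 80% female enrollment, phase-wise
# attrition and skewed weight-change distributions) and emit the CSV pair
# plus a provenance sidecar that step 3 consumes. Files go to
# scratch/cohort/ (regenerable; not a package artifact).

suppressPackageStartupMessages(library(reaim))

seed <- 20080115 %% 2^31
cfg <- default_study_config(seed = seed)
ds <- generate_cohort(cfg)
print(ds)

paths <- write_cohort(ds, "scratch/cohort", provenance = attr(ds, "provenance"))
cat("Wrote:\n")
for (p in paths) cat(" ", p, "\n")

p <- ds$participants
e1 <- phase_eligible(p$enrollment_date, 1, ds$data_collection_date)
cat(sprintf(
  "Cohort: %d participants (%.1f%% female), %d phase-I-eligible, %.1f%% completed phase I.\n",
  nrow(p), 100 * mean(p$sex == "female"), sum(e1),
  100 * mean(p$completed_phase1[e1])
))
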