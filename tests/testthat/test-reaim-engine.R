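test_that("the eligible denominator follows the prevalence arithmetic", {
  em <- eligibility_model(60041, 0.31, 0.36, 0.66)
  expect_equal(round(estimate_eligible(em)), 32878)
  expect_equal(estimate_eligible(eligibility_model(5000, 1, 0, 0.9)), 5000)
  expect_equal(estimate_eligible(eligibility_model(100, 0.5, 0.5, 0.5)), 75)
})

test_that("participation rate divides enrollment by the eligible estimate", {
  expect_equal(round(compute_ipr(1952, 32878.45), 3), 0.059)
  expect_equal(compute_ipr(1952, 60041 * 0.5476), 1952 / (60041 * 0.5476),
               tolerance = 1e-12)
  expect_equal(compute_ipr(1, 1), 1)
  expect_warning(capped <- compute_ipr(10, 5), "capped")
  expect_equal(capped, 1)
  expect_error(compute_ipr(0, 100), "positive")
})

test_that("differential effects aggregate by unweighted mean", {
  expect_equal(aggregate_differential(c(0.073, 0.113)), 0.093)
  expect_equal(aggregate_differential(c(0.050, 0.014)), 0.032)
  expect_equal(aggregate_differential(0.4), 0.4)
  expect_error(aggregate_differential(numeric(0)), "least one")
  expect_error(aggregate_differential(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("index formulas reproduce the published values at one decimal", {
  expect_equal(round(compute_reach(0.059, 0.093), 1), 5.4)
  expect_equal(compute_reach(0.3, 0), 30)
  expect_equal(compute_reach(0.5, 1), 0)
  expect_equal(round(compute_effectiveness(0.765, 0.592, 0.032), 1), 43.8)
  expect_equal(round(compute_effectiveness(0.457, 0.467, 0.008), 1), 21.2)
  expect_equal(compute_effectiveness(1, 1, 0), 100)
  expect_equal(round(compute_rate_index(31, 352), 1), 8.8)
  expect_equal(round(compute_rate_index(12.8, 14), 1), 91.4)
  expect_equal(round(compute_rate_index(14, 18), 1), 77.8)
  expect_error(compute_rate_index(15, 14), "numerator")
})

test_that("impacts multiply printed-precision indices and pair with zero as zero", {
  idx <- list(reach = 5.4, effectiveness = 43.8, adoption = 8.8,
              implementation = 91.4, maintenance_individual = 21.2,
              maintenance_setting = 77.8)
  imp <- compute_impacts(idx)
  expect_equal(round(unname(imp), 1), c(2.4, 8.0, 16.5))
  idx$effectiveness <- 0
  expect_equal(unname(compute_impacts(idx)[["impact_individual"]]), 0)
})

test_that("full component set reproduces every published index and impact", {
  ev <- reaim_evaluate(NULL, overrides = published_overrides())
  idx <- ev$indices
  expect_equal(round(idx$reach, 1), 5.4)
  expect_equal(round(idx$effectiveness, 1), 43.8)
  expect_equal(round(idx$adoption, 1), 8.8)
  expect_equal(round(idx$implementation, 1), 91.4)
  expect_equal(round(idx$maintenance_individual, 1), 21.2)
  expect_equal(round(idx$maintenance_setting, 1), 77.8)
  expect_equal(round(idx$impact_individual, 1), 2.4)
  expect_equal(round(idx$impact_setting, 1), 8.0)
  expect_equal(round(idx$impact_maintenance, 1), 16.5)
  expect_true(all(ev$provenance$source == "supplied"))
})

test_that("revised indices are non-negative for random component vectors", {
  set.seed(21)
  for (i in 1:1000) {
    v <- runif(11)
    comp <- component_values(v[1], v[2], v[3], v[4], v[5], v[6], v[7],
                             v[8], v[9], v[10], v[11], n_eligible = 1000)
    idx <- compute_indices(comp, round_indices = FALSE)
    vals <- unlist(idx)
    expect_true(all(vals >= 0 & vals <= 100))
    expect_lte(idx$impact_individual,
               min(idx$reach, idx$effectiveness) + 1e-9)
    expect_lte(idx$impact_setting,
               min(idx$adoption, idx$implementation) + 1e-9)
  }
})

test_that("effectiveness is monotone in its components", {
  set.seed(31)
  for (i in 1:100) {
    icr <- runif(1); o <- runif(1); di <- runif(1)
    eps <- runif(1, 0, 1 - max(icr, o, di))
    base <- compute_effectiveness(icr, o, di)
    expect_gte(compute_effectiveness(icr + eps, o, di), base)
    expect_gte(compute_effectiveness(icr, o + eps, di), base)
    expect_lte(compute_effectiveness(icr, o, di + eps), base)
  }
})

test_that("the legacy subtraction formula can go negative where the revision cannot", {
  comp <- component_values(
    ipr = 0.05, dr = 0.4, icr_phase1 = 0.5, outcome_phase1 = 0.1,
    di_phase1 = 0.3, spr = 0.1, cir = 0.9, icr_phase2 = 0.4,
    outcome_phase2 = 0.05, di_phase2 = 0.25, scr = 0.8, n_eligible = 100
  )
  legacy <- legacy_indices(comp)
  revised <- compute_indices(comp)
  expect_lt(legacy[["reach"]], 0)
  expect_lt(legacy[["effectiveness"]], 0)
  expect_true(all(unlist(revised) >= 0))
})

test_that("component bundles reject out-of-range values", {
  ov <- published_overrides()
  ov$dr <- 1.2
  expect_error(reaim_evaluate(NULL, overrides = ov), "\\[0, 1\\]")
  ov <- published_overrides()
  ov$bogus <- 1
  expect_error(reaim_evaluate(NULL, overrides = ov), "Unknown override")
  expect_error(reaim_evaluate(NULL, overrides = list(ipr = 0.1)), "missing")
})

test_that("a no-attrition cohort with saturated outcome scores 100 effectiveness", {
  cfg <- null_interaction_config(seed = 10, n = 600)
  cfg$completion_rates <- list(phase1 = c(female = 1, male = 1),
                               phase2 = c(female = 1, male = 1))
  ds <- generate_cohort(validate_simulation_config(cfg))
  ev <- reaim_evaluate(ds, overrides = list(outcome_phase1 = 1,
                                            di_phase1 = 0))
  expect_equal(ev$components$icr_phase1, 1)
  expect_equal(ev$indices$effectiveness, 100)
})

test_that("evaluation computes data-driven components with provenance", {
  ds <- generate_cohort(default_study_config(seed = 8, n_participants = 1500))
  ev <- reaim_evaluate(ds)
  expect_s3_class(ev$components, "component_values")
  comp_src <- ev$provenance$source[ev$provenance$component == "icr_phase1"]
  expect_equal(comp_src, "computed")
  # components land in sane calibrated neighborhoods
  expect_lt(abs(ev$components$icr_phase1 - 0.765), 0.06)
  expect_gt(ev$components$outcome_phase1, 0.3)
  expect_equal(ev$components$spr, 31 / 352)
  expect_true(ev$components$scr >= 0 && ev$components$scr <= 1)
  # mixing overrides keeps computed parts intact
  ev2 <- reaim_evaluate(ds, overrides = list(dr = 0.093))
  expect_equal(ev2$components$dr, 0.093)
  expect_equal(ev2$components$icr_phase1, ev$components$icr_phase1)
  expect_equal(
    ev2$provenance$source[ev2$provenance$component == "dr"], "supplied"
  )
})
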