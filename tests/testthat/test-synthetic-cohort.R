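test_that("the calibration config passes validation and carries the marginals", {
  cfg <- default_study_config(seed = 1)
  expect_s3_class(cfg, "simulation_config")
  expect_equal(cfg$enrollment_sex_split, 0.80)
  expect_equal(cfg$completion_rates$phase1[["female"]], 0.748)
  expect_equal(cfg$completion_rates$phase1[["male"]], 0.837)
  expect_equal(cfg$completion_rates$phase2[["female"]], 0.395)
  expect_equal(cfg$weight_change_model$phase1$female$median, -12.0)
  expect_equal(cfg$weight_change_model$phase1$male$median, -16.9)
  expect_equal(sum(cfg$site_component_prob), 12.8, tolerance = 1e-12)
  expect_equal(cfg$n_participants, 1952L)
})

test_that("invalid configurations fail before any sampling", {
  cfg <- default_study_config(seed = 1)
  cfg$enrollment_sex_split <- 1.2
  expect_error(validate_simulation_config(cfg), "\\[0, 1\\]")
  cfg <- default_study_config(seed = 1)
  cfg$site_component_prob <- rep(0.9, 13)
  expect_error(validate_simulation_config(cfg), "14")
  cfg <- default_study_config(seed = 1)
  cfg$enrollment_age_weights <- c(0.5, 0.5)
  expect_error(validate_simulation_config(cfg), "age groups")
  cfg <- default_study_config(seed = 1)
  cfg$interaction_magnitude <- -1
  expect_error(validate_simulation_config(cfg), "non-negative")
})

test_that("the same seed reproduces the cohort exactly; different seeds differ", {
  cfg <- default_study_config(seed = 42, n_participants = 400)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$participants, b$participants)
  expect_identical(a$sites, b$sites)
  c <- generate_cohort(default_study_config(seed = 43, n_participants = 400))
  expect_false(identical(a$participants$weight_lb_baseline,
                         c$participants$weight_lb_baseline))
})

test_that("unit completion probabilities make every eligible participant complete", {
  cfg <- default_study_config(seed = 9, n_participants = 500)
  cfg$completion_rates <- list(phase1 = c(female = 1, male = 1),
                               phase2 = c(female = 1, male = 1))
  ds <- generate_cohort(validate_simulation_config(cfg))
  p <- ds$participants
  e1 <- phase_eligible(p$enrollment_date, 1, ds$data_collection_date)
  e2 <- phase_eligible(p$enrollment_date, 2, ds$data_collection_date)
  expect_true(all(p$completed_phase1[e1]))
  expect_true(all(p$completed_phase2[e2]))
  expect_false(any(p$completed_phase1[!e1]))
})

test_that("realized completion converges to the configured rates", {
  ds <- generate_cohort(default_study_config(seed = 2, n_participants = 20000))
  p <- ds$participants
  e1 <- phase_eligible(p$enrollment_date, 1, ds$data_collection_date)
  e2 <- phase_eligible(p$enrollment_date, 2, ds$data_collection_date)
  for (sx in c("female", "male")) {
    target1 <- default_study_config(1)$completion_rates$phase1[[sx]]
    expect_lt(abs(mean(p$completed_phase1[e1 & p$sex == sx]) - target1), 0.02)
    target2 <- default_study_config(1)$completion_rates$phase2[[sx]]
    expect_lt(abs(mean(p$completed_phase2[e2 & p$sex == sx]) - target2), 0.02)
  }
})

test_that("baseline weight matches the configured skewed marginals", {
  ds <- generate_cohort(default_study_config(seed = 4, n_participants = 2000))
  p <- ds$participants
  wf <- p$weight_lb_baseline[p$sex == "female"]
  expect_lt(abs(median(wf, na.rm = TRUE) - 220.8), 5)
  s <- summarize_measure(stats::na.omit(wf))
  expect_gt(s$skewness, 0) # right-skewed, as log-normal baselines should be
})

test_that("a null group-by-time configuration yields a negligible interaction", {
  ds <- generate_cohort(null_interaction_config(seed = 31, n = 5000))
  p <- ds$participants
  comp <- p$completed_phase1 & !is.na(p$weight_lb_baseline)
  res <- rm_anova_two_timepoints(p$weight_lb_baseline[comp],
                                 p$weight_lb_p1[comp], p$sex[comp])
  expect_lt(res$eta2_interaction, 0.01)
})

test_that("the estimated interaction grows with the configured sex shift", {
  etas <- vapply(c(0, 6, 15), function(d) {
    cfg <- null_interaction_config(seed = 12, n = 4000)
    cfg$interaction_magnitude <- d
    ds <- generate_cohort(validate_simulation_config(cfg))
    p <- ds$participants
    comp <- p$completed_phase1 & !is.na(p$weight_lb_baseline)
    rm_anova_two_timepoints(p$weight_lb_baseline[comp],
                            p$weight_lb_p1[comp],
                            p$sex[comp])$eta2_interaction
  }, numeric(1))
  expect_true(all(diff(etas) > 0))
})

test_that("generated cohorts satisfy the data-model invariants", {
  ds <- generate_cohort(default_study_config(seed = 6, n_participants = 800))
  p <- ds$participants
  expect_true(all(p$age_years >= 18))
  expect_true(all(p$completed_phase1[p$completed_phase2]))
  expect_true(all(!is.na(p$weight_lb_p1[p$completed_phase1])))
  expect_true(all(p$site_id %in% ds$sites$site_id))
  expect_true(all(p$enrollment_date <= ds$data_collection_date))
  expect_equal(nrow(ds$sites), 31)
  prov <- attr(ds, "provenance")
  expect_equal(prov$seed, 6L)
  expect_match(prov$config_hash, "^[0-9a-f]+$")
})
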