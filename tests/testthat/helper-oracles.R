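# Independent oracles and fixture builders used across the suite.

# Brute-force unweighted-means mixed ANOVA (group x time, subjects nested in
# group, two time levels), computed literally from cell means, subject
# means and the unweighted grand mean. Kept deliberately naive and separate
# from the package's difference-score implementation.
oracle_mixed_anova <- function(baseline, followup, groups = NULL) {
  if (is.null(groups)) groups <- rep("all", length(baseline))
  g <- factor(groups)
  k <- nlevels(g)
  y <- cbind(baseline, followup)
  n_j <- as.vector(table(g))
  n_h <- k / sum(1 / n_j)

  cell_means <- matrix(NA_real_, k, 2)
  for (j in seq_len(k)) {
    for (t in 1:2) cell_means[j, t] <- mean(y[g == levels(g)[j], t])
  }
  group_means <- rowMeans(cell_means)       # unweighted over time
  time_means <- colMeans(cell_means)        # unweighted over groups
  grand <- mean(cell_means)

  ss_time <- n_h * k * sum((time_means - grand)^2)
  ss_int <- 0
  for (j in seq_len(k)) {
    for (t in 1:2) {
      ss_int <- ss_int +
        n_h * (cell_means[j, t] - group_means[j] - time_means[t] + grand)^2
    }
  }
  subj_means <- rowMeans(y)
  ss_err <- 0
  for (i in seq_along(baseline)) {
    j <- as.integer(g[i])
    for (t in 1:2) {
      ss_err <- ss_err +
        (y[i, t] - subj_means[i] - cell_means[j, t] + group_means[j])^2
    }
  }
  list(ss_time = unname(ss_time), ss_interaction = unname(ss_int),
       ss_within_error = unname(ss_err))
}

# One-way unweighted-means ANOVA F on difference scores.
oracle_diff_score_f <- function(d, groups) {
  g <- factor(groups)
  k <- nlevels(g)
  m <- tapply(d, g, mean)
  n_h <- k / sum(1 / table(g))
  u <- mean(m)
  ms_between <- n_h * sum((m - u)^2) / (k - 1)
  ms_within <- sum((d - m[g])^2) / (length(d) - k)
  ms_between / ms_within
}

# Adjusted (SPSS/SAS) sample skewness, written out from its formula.
oracle_skewness <- function(x) {
  n <- length(x)
  z <- (x - mean(x)) / sd(x)
  n / ((n - 1) * (n - 2)) * sum(z^3)
}

# Pearson chi-square by literal expansion of sum((O - E)^2 / E).
oracle_chi2 <- function(tab) {
  n <- sum(tab)
  out <- 0
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      e <- sum(tab[i, ]) * sum(tab[, j]) / n
      out <- out + (tab[i, j] - e)^2 / e
    }
  }
  out
}

# Random contingency table with no zero margins.
random_table <- function(nr, nc) {
  repeat {
    tab <- matrix(rpois(nr * nc, lambda = 8), nr, nc)
    if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) return(tab)
  }
}

# Minimal hand-built cohort tables for I/O and validation tests.
tiny_participants <- function() {
  tibble::tibble(
    participant_id = c("P1", "P2", "P3"),
    site_id = c("S1", "S1", "S2"),
    sex = c("female", "male", "female"),
    age_years = c(44.2, 61.0, 29.5),
    enrollment_date = as.Date(c("2006-03-01", "2007-05-20", "2007-11-30")),
    height_in = c(64, 71, 66),
    weight_lb_baseline = c(210.5, NA, 188.0),
    weight_lb_p1 = c(199.0, 250.2, NA),
    weight_lb_p2 = c(NA_real_, NA_real_, NA_real_),
    bmi_baseline = c(36.1, NA, 30.3),
    bmi_p1 = c(34.2, 34.9, NA),
    bmi_p2 = c(NA_real_, NA_real_, NA_real_),
    sbp_baseline = c(128, 135, NA),
    sbp_p1 = c(121, 130, NA), sbp_p2 = c(NA_real_, NA_real_, NA_real_),
    dbp_baseline = c(81, 84, 78),
    dbp_p1 = c(78, 80, NA), dbp_p2 = c(NA_real_, NA_real_, NA_real_),
    bodyfat_baseline = c(46.0, 35.2, NA),
    bodyfat_p1 = c(44.1, 33.0, NA),
    bodyfat_p2 = c(NA_real_, NA_real_, NA_real_),
    waist_baseline = c(43.5, 48.0, 39.0),
    waist_p1 = c(41.0, 45.5, NA),
    waist_p2 = c(NA_real_, NA_real_, NA_real_),
    completed_phase1 = c(TRUE, TRUE, FALSE),
    completed_phase2 = c(FALSE, FALSE, FALSE)
  )
}

tiny_sites <- function() {
  comp <- stats::setNames(as.list(rep(TRUE, 14)), sprintf("comp_%02d", 1:14))
  dplyr::bind_cols(
    tibble::tibble(
      site_id = c("S1", "S2"),
      site_type = c("hospital", "fitness_center"),
      approval_date = as.Date(c("2005-06-01", "2007-09-01"))
    ),
    tibble::as_tibble(comp),
    tibble::tibble(still_accepting = c(TRUE, TRUE))
  )
}

tiny_config <- function() {
  list(
    n_adult_members = 60041, p_obese = 0.31, p_overweight = 0.36,
    p_comorbid_overweight = 0.66, eligible_sex_split = 0.541,
    eligible_age_distribution = c(0.04, 0.13, 0.20, 0.24, 0.21, 0.18),
    data_collection_date = "2008-01-15", n_potential_sites = 352
  )
}

tiny_cohort <- function() {
  cohort_dataset(
    participants = tiny_participants(),
    sites = tiny_sites(),
    eligibility = eligibility_model(60041, 0.31, 0.36, 0.66),
    data_collection_date = as.Date("2008-01-15"),
    n_potential_sites = 352
  )
}

# Printed component set of the canonical evaluation (used as overrides).
published_overrides <- function() {
  list(
    ipr = 0.059, dr = 0.093,
    icr_phase1 = 0.765, outcome_phase1 = 0.592, di_phase1 = 0.032,
    spr = 0.088, cir = 0.914,
    icr_phase2 = 0.457, outcome_phase2 = 0.467, di_phase2 = 0.008,
    scr = 0.778, n_eligible = 32878
  )
}

# Null-calibrated config: identical per-sex change models and no induced
# group-by-time shift, for interaction-eta2 null checks.
null_interaction_config <- function(seed, n) {
  cfg <- default_study_config(seed = seed, n_participants = n)
  cfg$weight_change_model$phase1$male <- cfg$weight_change_model$phase1$female
  cfg$weight_change_model$phase2$male <- cfg$weight_change_model$phase2$female
  cfg$completion_rates <- list(phase1 = c(female = 0.8, male = 0.8),
                               phase2 = c(female = 0.45, male = 0.45))
  cfg$interaction_magnitude <- 0
  validate_simulation_config(cfg)
}
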