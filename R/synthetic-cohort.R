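# Synthetic cohort generator. Emulates the statistical structure the
# evaluation assumes — sex- and age-biased enrollment, skewed (log-normal)
# baseline weight, phase-wise Bernoulli attrition differing by sex, and
# skewed weight-change distributions with an optional group-by-time shift —
# so the full pipeline is testable without the proprietary claims database.

# Fixed offsets deriving one sub-stream per generated block from the single
# configured seed, so adding a block never perturbs earlier draws.
SUBSTREAM <- c(demographics = 1L, dates = 2L, baselines = 3L,
               completion = 4L, changes = 5L, secondary = 6L,
               missingness = 7L, sites = 8L)

substream_seed <- function(seed, block) {
  # double arithmetic keeps the product exact well past .Machine$integer.max
  as.integer((as.numeric(seed) * 131 + SUBSTREAM[[block]]) %% 2147483629)
}

med_iqr <- function(median, iqr_low, iqr_high) {
  list(median = median, iqr_low = iqr_low, iqr_high = iqr_high)
}

mean_sd <- function(mean, sd) list(mean = mean, sd = sd)

#' Simulation configuration
#'
#' Assembles and validates the parameter bundle for [generate_cohort()].
#' Distributional choices: baseline weight is log-normal per sex with
#' mu/sigma solved from the stated median and interquartile range; weight
#' change is a location minus a gamma draw (shape `gamma_shape`), giving the
#' left-skewed loss distributions seen in practice, with location and scale
#' matched to the stated change median and IQR; completion is independent
#' Bernoulli given sex (optionally adjusted by age group), with phase-II
#' completion drawn conditionally on phase-I completion so the configured
#' phase-II rate is the marginal rate among phase-II-eligible participants.
#'
#' @param seed Integer seed; all randomness derives from it.
#' @param n_participants,n_sites,n_potential_sites Cohort dimensions.
#' @param data_collection_date Snapshot date.
#' @param enrollment_sex_split Proportion of enrollees who are female.
#' @param enrollment_age_weights Probabilities over the six age groups.
#' @param baseline_weight_model Per-sex `list(median, iqr_low, iqr_high)`
#'   (lb).
#' @param height_model Per-sex `list(mean, sd)` (in).
#' @param completion_rates `list(phase1 = c(female=, male=), phase2 = ...)`;
#'   phase-II entries are marginal rates among phase-II-eligible.
#' @param completion_age_adjust Additive per-age-group adjustment to the
#'   completion probability (clipped to \[0, 1\]); default none.
#' @param weight_change_model Per-phase, per-sex
#'   `list(median, iqr_low, iqr_high)` of the change from baseline (lb;
#'   negative = loss).
#' @param gamma_shape Shape of the gamma loss kernel (> 0).
#' @param interaction_magnitude Extra mean weight change (lb) subtracted for
#'   male completers, inducing a sex-by-time interaction; 0 = none beyond
#'   what the per-sex locations already encode.
#' @param secondary_model Baseline `list(mean, sd)` and per-phase change
#'   `list(mean, sd)` per sex for sbp, dbp, bodyfat, waist.
#' @param missing_rates Per-measure missingness probabilities.
#' @param eligible_fracs `c(phase2 =, phase1_only =)`: fractions of
#'   enrollees whose enrollment dates make them phase-II-eligible or only
#'   phase-I-eligible (the rest enrolled within 12 weeks of collection).
#' @param site_component_prob Length-14 probabilities that a site delivers
#'   each protocol component.
#' @param site_continuation_prob Probability a mature site (approved >= 1
#'   year before collection) still accepts participants.
#' @param frac_sites_mature Fraction of sites approved >= 1 year before
#'   collection.
#' @param site_type_probs Probabilities over the four site types.
#' @param eligibility An [eligibility_model()].
#' @param age_breaks Age-group lower bounds.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(seed,
                              n_participants,
                              n_sites,
                              n_potential_sites,
                              data_collection_date,
                              enrollment_sex_split,
                              enrollment_age_weights,
                              baseline_weight_model,
                              height_model,
                              completion_rates,
                              weight_change_model,
                              eligibility,
                              completion_age_adjust = NULL,
                              gamma_shape = 2,
                              interaction_magnitude = 0,
                              secondary_model = NULL,
                              missing_rates = NULL,
                              eligible_fracs = c(phase2 = 0.39,
                                                 phase1_only = 0.45),
                              site_component_prob = rep(12.8 / 14, 14),
                              site_continuation_prob = 14 / 18,
                              frac_sites_mature = 18 / 31,
                              site_type_probs = c(cardiac_rehab = 2,
                                                  physical_therapy = 2,
                                                  hospital = 5,
                                                  fitness_center = 22) / 31,
                              age_breaks = DEFAULT_AGE_BREAKS) {
  cfg <- structure(
    list(
      seed = as.integer(seed),
      n_participants = n_participants,
      n_sites = n_sites,
      n_potential_sites = n_potential_sites,
      data_collection_date = as.Date(data_collection_date),
      enrollment_sex_split = enrollment_sex_split,
      enrollment_age_weights = enrollment_age_weights,
      baseline_weight_model = baseline_weight_model,
      height_model = height_model,
      completion_rates = completion_rates,
      completion_age_adjust = completion_age_adjust,
      weight_change_model = weight_change_model,
      gamma_shape = gamma_shape,
      interaction_magnitude = interaction_magnitude,
      secondary_model = secondary_model,
      missing_rates = missing_rates,
      eligible_fracs = eligible_fracs,
      site_component_prob = site_component_prob,
      site_continuation_prob = site_continuation_prob,
      frac_sites_mature = frac_sites_mature,
      site_type_probs = site_type_probs,
      eligibility = eligibility,
      age_breaks = age_breaks
    ),
    class = "simulation_config"
  )
  validate_simulation_config(cfg)
}

#' @rdname simulation_config
#' @param config A `simulation_config` to validate.
#' @export
validate_simulation_config <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with(config, {
    if (n_participants < 1 || n_sites < 1 || n_potential_sites < n_sites) {
      abort("Cohort dimensions are inconsistent.")
    }
    probs <- c(enrollment_sex_split, enrollment_age_weights,
               eligible_fracs, site_component_prob, site_continuation_prob,
               frac_sites_mature, site_type_probs,
               unlist(completion_rates))
    if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
      abort("All probabilities must lie in [0, 1].")
    }
    if (length(enrollment_age_weights) != length(age_breaks)) {
      abort("`enrollment_age_weights` must match the age groups.")
    }
    if (abs(sum(enrollment_age_weights) - 1) > 1e-9) {
      abort("`enrollment_age_weights` must sum to 1.")
    }
    if (sum(eligible_fracs) > 1 + 1e-12) {
      abort("`eligible_fracs` must sum to at most 1.")
    }
    if (length(site_component_prob) != 14) {
      abort("`site_component_prob` must have exactly 14 entries.")
    }
    if (gamma_shape <= 0) abort("`gamma_shape` must be positive.")
    if (interaction_magnitude < 0) {
      abort("`interaction_magnitude` must be non-negative.")
    }
    for (ph in c("phase1", "phase2")) {
      r <- completion_rates[[ph]]
      if (is.null(r) || !all(c("female", "male") %in% names(r))) {
        abort(paste0("`completion_rates$", ph,
                     "` needs `female` and `male` entries."))
      }
      for (sx in SEX_LEVELS) {
        m <- weight_change_model[[ph]][[sx]]
        if (is.null(m) || m$iqr_low > m$median || m$median > m$iqr_high) {
          abort(paste0("Change model for ", ph, "/", sx,
                       " needs iqr_low <= median <= iqr_high."))
        }
      }
    }
    for (sx in SEX_LEVELS) {
      b <- baseline_weight_model[[sx]]
      if (is.null(b) || b$iqr_low <= 0 || b$iqr_low > b$median ||
          b$median > b$iqr_high) {
        abort(paste0("Baseline weight model for ", sx, " is invalid."))
      }
    }
  })
  validate_eligibility_model(config$eligibility)
  config
}

#' Calibration configuration for the canonical program
#'
#' The default study conditions: 1,952 enrollees at 31 of 352 potential
#' sites, 80.0% female enrollment against a 54.1%-female eligible pool,
#' log-normal baseline weight with female median 220.8 lb (IQR 192.0-258.4)
#' and male median 269.9 lb (IQR 232.7-333.8), phase-I completion 74.8%
#' (women) / 83.7% (men) and phase-II 39.5% / 51.4%, phase-I median weight
#' change -12.0 lb (women) / -16.9 lb (men) and phase-II -15.3 / -14.8 lb,
#' enrollment dates spread so 1,647/1,952 enrollees are phase-I-eligible
#' and 762/1,952 phase-II-eligible, site component probabilities summing to
#' 12.8 of 14 (home exercise logs the weakest at .65), and 14/18 mature-site
#' continuation.
#'
#' @param seed Integer seed.
#' @param n_participants Cohort size (default the canonical 1,952).
#' @return A validated [simulation_config()].
#' @export
default_study_config <- function(seed = 1L, n_participants = 1952L) {
  # 14 component probabilities: nine universally delivered, home exercise
  # logs at .65, the remaining four set so the expected total is 12.8.
  comp_prob <- c(rep(1, 9), 0.65, rep((12.8 - 9 - 0.65) / 4, 4))
  simulation_config(
    seed = seed,
    n_participants = n_participants,
    n_sites = 31L,
    n_potential_sites = 352L,
    data_collection_date = as.Date("2008-01-15"),
    enrollment_sex_split = 0.80,
    enrollment_age_weights = c(0.01, 0.08, 0.23, 0.40, 0.24, 0.04),
    baseline_weight_model = list(
      female = med_iqr(220.8, 192.0, 258.4),
      male = med_iqr(269.9, 232.7, 333.8)
    ),
    height_model = list(
      female = mean_sd(64.4, 2.2),
      male = mean_sd(71.0, 3.0)
    ),
    completion_rates = list(
      phase1 = c(female = 0.748, male = 0.837),
      phase2 = c(female = 0.395, male = 0.514)
    ),
    weight_change_model = list(
      phase1 = list(
        female = med_iqr(-12.0, -19.8, -6.0),
        male = med_iqr(-16.9, -29.3, -8.0)
      ),
      phase2 = list(
        female = med_iqr(-15.3, -28.6, -6.3),
        male = med_iqr(-14.8, -36.3, -5.2)
      )
    ),
    secondary_model = list(
      sbp = list(
        baseline = list(female = mean_sd(126.8, 13.3),
                        male = mean_sd(130.2, 14.8)),
        phase1 = list(female = mean_sd(-5.0, 16.1),
                      male = mean_sd(-7.3, 13.6)),
        phase2 = list(female = mean_sd(-5.3, 17.0),
                      male = mean_sd(-7.1, 14.7))
      ),
      dbp = list(
        baseline = list(female = mean_sd(80.5, 9.9),
                        male = mean_sd(82.1, 9.8)),
        phase1 = list(female = mean_sd(-3.4, 10.5),
                      male = mean_sd(-4.6, 9.7)),
        phase2 = list(female = mean_sd(-6.3, 11.2),
                      male = mean_sd(-6.4, 10.4))
      ),
      bodyfat = list(
        baseline = list(female = mean_sd(45.5, 5.6),
                        male = mean_sd(36.5, 8.3)),
        phase1 = list(female = mean_sd(-2.0, 3.2),
                      male = mean_sd(-3.6, 4.9)),
        phase2 = list(female = mean_sd(-2.7, 4.5),
                      male = mean_sd(-2.9, 6.6))
      ),
      waist = list(
        baseline = list(female = mean_sd(43.1, 6.6),
                        male = mean_sd(48.2, 7.0)),
        phase1 = list(female = mean_sd(-2.7, 2.2),
                      male = mean_sd(-2.8, 2.5)),
        phase2 = list(female = mean_sd(-4.0, 3.4),
                      male = mean_sd(-3.4, 2.9))
      )
    ),
    missing_rates = list(
      weight_baseline = 0.085,
      sbp = 0.13, dbp = 0.13, bodyfat = 0.23, waist = 0.44
    ),
    eligible_fracs = c(phase2 = 762 / 1952,
                       phase1_only = (1647 - 762) / 1952),
    site_component_prob = comp_prob,
    site_continuation_prob = 14 / 18,
    frac_sites_mature = 18 / 31,
    eligibility = eligibility_model(
      n_adult_members = 60041L,
      p_obese = 0.31,
      p_overweight = 0.36,
      p_comorbid_overweight = 0.66,
      eligible_sex_split = 0.541,
      eligible_age_distribution = c(0.04, 0.13, 0.20, 0.24, 0.21, 0.18)
    )
  )
}

# Solve log-normal (mu, sigma) from a median and IQR: mu = log(median),
# sigma = log(q75/q25) / (2 * qnorm(.75)).
lognormal_params <- function(m) {
  list(mu = log(m$median),
       sigma = log(m$iqr_high / m$iqr_low) / (2 * stats::qnorm(0.75)))
}

# Change = location - gamma(shape, scale): scale matches the IQR width,
# location matches the median.
gamma_change_params <- function(m, shape) {
  qs <- qgamma(c(0.25, 0.5, 0.75), shape = shape, scale = 1)
  scale <- (m$iqr_high - m$iqr_low) / (qs[3] - qs[1])
  list(location = m$median + scale * qs[2], scale = scale, shape = shape)
}

draw_change <- function(n, m, shape, extra_shift = 0) {
  p <- gamma_change_params(m, shape)
  p$location - extra_shift - rgamma(n, shape = p$shape, scale = p$scale)
}

#' Generate a synthetic cohort
#'
#' Deterministic for a fixed seed (one sub-stream per generated block).
#' Participants receive sex and age group from the enrollment weights (age
#' uniform within group, the open-ended group spanning 65-80), a site
#' uniformly at random, an enrollment date placing them in the configured
#' phase-eligibility stratum, a log-normal baseline weight, Bernoulli
#' phase-I completion at the configured per-sex rate among phase-I-eligible
#' records, conditional phase-II completion so the marginal phase-II rate
#' matches, and end-of-phase weights equal to baseline plus a skewed
#' (gamma) change draw whose male location is shifted by
#' `interaction_magnitude`. Sites draw their 14 protocol components
#' independently and their continuation status by maturity stratum. BMI is
#' derived as `703 * weight / height^2` at every timepoint.
#'
#' @param config A validated [simulation_config()].
#' @return A `cohort_dataset` whose `provenance` attribute records the seed
#'   and configuration hash.
#' @export
#' @examples
#' ds <- generate_cohort(default_study_config(seed = 7, n_participants = 300))
#' ds
generate_cohort <- function(config) {
  config <- validate_simulation_config(config)
  n <- config$n_participants

  # sites ------------------------------------------------------------------
  set.seed(substream_seed(config$seed, "sites"))
  n_s <- config$n_sites
  site_ids <- sprintf("S%03d", seq_len(n_s))
  site_type <- sample(names(config$site_type_probs), n_s, replace = TRUE,
                      prob = config$site_type_probs)
  mature <- runif(n_s) < config$frac_sites_mature
  days_before <- ifelse(mature,
                        floor(runif(n_s, 365, 1826)),
                        floor(runif(n_s, 30, 365)))
  approval_date <- config$data_collection_date - days_before
  comp <- sapply(config$site_component_prob,
                 function(p) runif(n_s) < p)
  comp <- matrix(comp, nrow = n_s)
  colnames(comp) <- sprintf("comp_%02d", 1:14)
  still <- ifelse(mature,
                  runif(n_s) < config$site_continuation_prob,
                  TRUE)
  sites <- dplyr::bind_cols(
    tibble(site_id = site_ids, site_type = site_type,
           approval_date = approval_date),
    as_tibble(comp),
    tibble(still_accepting = as.logical(still))
  )

  # demographics ------------------------------------------------------------
  set.seed(substream_seed(config$seed, "demographics"))
  sex <- ifelse(runif(n) < config$enrollment_sex_split, "female", "male")
  breaks <- config$age_breaks
  uppers <- c(breaks[-1], 80)  # open-ended top group capped for sampling
  grp <- sample.int(length(breaks), n, replace = TRUE,
                    prob = config$enrollment_age_weights)
  age <- runif(n, breaks[grp], uppers[grp])
  site_id <- sample(site_ids, n, replace = TRUE)

  # enrollment dates --------------------------------------------------------
  set.seed(substream_seed(config$seed, "dates"))
  strat <- sample(c("phase2", "phase1_only", "recent"), n, replace = TRUE,
                  prob = c(config$eligible_fracs[["phase2"]],
                           config$eligible_fracs[["phase1_only"]],
                           1 - sum(config$eligible_fracs)))
  days <- numeric(n)
  days[strat == "phase2"] <- floor(runif(sum(strat == "phase2"), 365, 1400))
  days[strat == "phase1_only"] <-
    floor(runif(sum(strat == "phase1_only"), 84, 365))
  days[strat == "recent"] <- floor(runif(sum(strat == "recent"), 0, 84))
  enrollment_date <- config$data_collection_date - days

  # baseline measurements ----------------------------------------------------
  set.seed(substream_seed(config$seed, "baselines"))
  weight0 <- height <- numeric(n)
  for (sx in SEX_LEVELS) {
    idx <- sex == sx
    lp <- lognormal_params(config$baseline_weight_model[[sx]])
    weight0[idx] <- rlnorm(sum(idx), lp$mu, lp$sigma)
    hm <- config$height_model[[sx]]
    height[idx] <- rnorm(sum(idx), hm$mean, hm$sd)
  }

  # completion ---------------------------------------------------------------
  set.seed(substream_seed(config$seed, "completion"))
  elig1 <- phase_eligible(enrollment_date, 1, config$data_collection_date)
  elig2 <- phase_eligible(enrollment_date, 2, config$data_collection_date)
  p1 <- config$completion_rates$phase1[sex]
  p2 <- config$completion_rates$phase2[sex]
  if (!is.null(config$completion_age_adjust)) {
    adj <- config$completion_age_adjust[grp]
    p1 <- pmin(1, pmax(0, p1 + adj))
  }
  completed1 <- elig1 & (runif(n) < p1)
  # conditional rate so the marginal among phase-II-eligible is p2
  p2_cond <- pmin(1, ifelse(p1 > 0, p2 / p1, 0))
  completed2 <- completed1 & elig2 & (runif(n) < p2_cond)

  # weight changes -----------------------------------------------------------
  set.seed(substream_seed(config$seed, "changes"))
  weight1 <- weight2 <- rep(NA_real_, n)
  for (sx in SEX_LEVELS) {
    shift <- if (sx == "male") config$interaction_magnitude else 0
    i1 <- which(completed1 & sex == sx)
    weight1[i1] <- weight0[i1] + draw_change(
      length(i1), config$weight_change_model$phase1[[sx]],
      config$gamma_shape, shift
    )
    i2 <- which(completed2 & sex == sx)
    weight2[i2] <- weight0[i2] + draw_change(
      length(i2), config$weight_change_model$phase2[[sx]],
      config$gamma_shape, shift
    )
  }
  weight1 <- pmax(weight1, 80)
  weight2 <- pmax(weight2, 80)

  # secondary measurements ----------------------------------------------------
  set.seed(substream_seed(config$seed, "secondary"))
  sec <- list()
  if (!is.null(config$secondary_model)) {
    for (ms in names(config$secondary_model)) {
      mdl <- config$secondary_model[[ms]]
      base <- chg1 <- chg2 <- numeric(n)
      for (sx in SEX_LEVELS) {
        idx <- sex == sx
        base[idx] <- rnorm(sum(idx), mdl$baseline[[sx]]$mean,
                           mdl$baseline[[sx]]$sd)
        chg1[idx] <- rnorm(sum(idx), mdl$phase1[[sx]]$mean,
                           mdl$phase1[[sx]]$sd)
        chg2[idx] <- rnorm(sum(idx), mdl$phase2[[sx]]$mean,
                           mdl$phase2[[sx]]$sd)
      }
      sec[[paste0(ms, "_baseline")]] <- base
      sec[[paste0(ms, "_p1")]] <- ifelse(completed1, base + chg1, NA_real_)
      sec[[paste0(ms, "_p2")]] <- ifelse(completed2, base + chg2, NA_real_)
    }
  } else {
    for (ms in c("sbp", "dbp", "bodyfat", "waist")) {
      for (tp in TIMEPOINTS) sec[[paste0(ms, "_", tp)]] <- rep(NA_real_, n)
    }
  }

  # missingness ---------------------------------------------------------------
  set.seed(substream_seed(config$seed, "missingness"))
  mr <- config$missing_rates
  weight0_obs <- weight0
  if (!is.null(mr$weight_baseline) && mr$weight_baseline > 0) {
    weight0_obs[runif(n) < mr$weight_baseline] <- NA_real_
  }
  for (ms in c("sbp", "dbp", "bodyfat", "waist")) {
    rate <- mr[[ms]] %||% 0
    if (rate > 0) {
      for (tp in TIMEPOINTS) {
        col <- paste0(ms, "_", tp)
        sec[[col]][runif(n) < rate] <- NA_real_
      }
    }
  }

  participants <- dplyr::bind_cols(
    tibble(
      participant_id = sprintf("P%05d", seq_len(n)),
      site_id = site_id,
      sex = sex,
      age_years = round(age, 1),
      enrollment_date = enrollment_date,
      height_in = round(height, 1),
      weight_lb_baseline = round(weight0_obs, 1),
      weight_lb_p1 = round(weight1, 1),
      weight_lb_p2 = round(weight2, 1)
    ),
    as_tibble(lapply(sec, round, 1)),
    tibble(
      completed_phase1 = completed1,
      completed_phase2 = completed2
    )
  )
  participants$bmi_baseline <-
    round(703 * participants$weight_lb_baseline / participants$height_in^2, 1)
  participants$bmi_p1 <-
    round(703 * participants$weight_lb_p1 / participants$height_in^2, 1)
  participants$bmi_p2 <-
    round(703 * participants$weight_lb_p2 / participants$height_in^2, 1)

  ds <- cohort_dataset(
    participants = participants,
    sites = sites,
    eligibility = config$eligibility,
    data_collection_date = config$data_collection_date,
    n_potential_sites = config$n_potential_sites,
    age_breaks = config$age_breaks,
    bmi_tolerance = 0.5
  )
  attr(ds, "provenance") <- list(
    seed = config$seed,
    config_hash = rlang::hash(config),
    generator = paste0("reaim ", as.character(utils::packageVersion("reaim")))
  )
  ds
}
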