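# Bounded standardized effect sizes feeding the index formulas: squared
# Cramer phi from contingency tables and partial eta squared from
# two-timepoint repeated-measures / mixed ANOVA, plus the descriptive
# summaries used in the outcome tables.

#' Squared Cramer phi from a contingency table
#'
#' Pearson chi-square (no continuity correction) with the squared Cramer phi
#' effect size, `phi_c2 = chi2 / (n * (min(r, c) - 1))`, which is bounded in
#' \[0, 1\] for every table and reduces to the classical `phi^2 = chi2 / n`
#' for 2 x 2 tables. Interpretation benchmarks: ~.01 small, ~.09 moderate,
#' >.25 large.
#'
#' @param table Matrix of non-negative counts, at least 2 x 2, with no
#'   all-zero row or column.
#' @return A `contingency_result`: list with `chi2`, `df`, `n`, `p_value`,
#'   `phi_c2`.
#' @export
#' @examples
#' chi_square_phi2(matrix(c(993, 335, 267, 52), nrow = 2, byrow = TRUE))
chi_square_phi2 <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) < 2 || ncol(table) < 2) {
    abort("Contingency table must have at least 2 rows and 2 columns.")
  }
  if (any(table < 0) || any(!is.finite(table))) {
    abort("Counts must be finite and non-negative.")
  }
  if (sum(table) < 1) abort("Total count must be at least 1.")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    abort("Degenerate table: all-zero row or column margin.")
  }
  ct <- suppressWarnings(chisq.test(table, correct = FALSE))
  n <- sum(table)
  k <- min(dim(table)) - 1
  structure(
    list(
      chi2 = unname(ct$statistic),
      df = unname(ct$parameter),
      n = n,
      p_value = unname(ct$p.value),
      phi_c2 = unname(ct$statistic) / (n * k)
    ),
    class = "contingency_result"
  )
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(sprintf("chi2(%d, N = %d) = %.3f, p = %.4g, phi_c2 = %.4f\n",
              x$df, x$n, x$chi2, x$p_value, x$phi_c2))
  invisible(x)
}

#' Demographic representativeness as squared Cramer phi
#'
#' Compares the demographic composition of program enrollees with that of
#' the eligible population by building a participant-versus-nonparticipant
#' by category contingency table: row one holds the enrolled counts, row two
#' the remaining eligible individuals, `round(n_eligible * p_k) -
#' enrolled_k` per category. The squared Cramer phi of that table measures
#' how unrepresentative enrollment is (0 = perfectly representative).
#'
#' This construction is one convention among several the underlying
#' comparison admits (the comparison population could instead be the full
#' eligible pool including enrollees); published representativeness values
#' are therefore accepted as overrides in [reaim_evaluate()], and results
#' carry a `convention` note.
#'
#' @param enrolled_counts Named or unnamed integer vector of enrollee counts
#'   per category.
#' @param eligible_proportions Proportions of the eligible population per
#'   category, summing to 1.
#' @param n_eligible Size of the eligible population.
#' @return A `contingency_result` with a `convention` attribute.
#' @export
representativeness_phi2 <- function(enrolled_counts, eligible_proportions,
                                    n_eligible) {
  if (length(enrolled_counts) != length(eligible_proportions)) {
    abort("Enrolled counts and eligible proportions must align.")
  }
  if (abs(sum(eligible_proportions) - 1) > 1e-6) {
    abort("`eligible_proportions` must sum to 1.")
  }
  if (sum(enrolled_counts) > n_eligible) {
    abort("Enrolled total exceeds the eligible population.")
  }
  zero_mass <- eligible_proportions == 0 & enrolled_counts > 0
  if (any(zero_mass)) {
    abort("Category with zero eligible mass but non-zero enrollment.")
  }
  eligible_counts <- round(n_eligible * eligible_proportions)
  nonparticipants <- eligible_counts - enrolled_counts
  if (any(nonparticipants < 0)) {
    abort("Enrollment exceeds the eligible count in some category.")
  }
  res <- chi_square_phi2(rbind(enrolled = enrolled_counts,
                               nonparticipant = nonparticipants))
  attr(res, "convention") <- "participant_vs_nonparticipant"
  res
}

#' Two-timepoint repeated-measures / mixed ANOVA
#'
#' Decomposes baseline and follow-up measurements into time,
#' group-by-time interaction and within-subject error sums of squares, with
#' partial eta squared effect sizes `SS_effect / (SS_effect + SS_error)`.
#' With two timepoints the within-subject decomposition is a function of the
#' per-subject change score `d = followup - baseline` (on the normalized
#' contrast `d / sqrt(2)`), which is the route used here.
#'
#' Without `group_labels` the model is one-way repeated measures; the time F
#' equals the squared paired t statistic and `eta2_time = t^2 / (t^2 + n -
#' 1)`. With groups, a mixed model with one between-subjects factor is
#' fitted using the unweighted-means (Type III) convention, appropriate for
#' the strongly unbalanced group sizes that arise in cohort attrition data:
#' marginal means average group means with equal weight and sums of squares
#' use the harmonic mean of the group sizes.
#'
#' Rows with a missing baseline or follow-up are dropped (pairwise-complete
#' analysis); if both timepoints have zero variance the fit is degenerate
#' and returns zero effect sizes with `degenerate = TRUE`.
#'
#' @param baseline,followup Numeric vectors of equal length.
#' @param group_labels Optional vector of group labels (every retained group
#'   must have at least 2 members).
#' @return An `rm_anova_result`: list with sums of squares, F statistics,
#'   p-values, `eta2_time`, `eta2_interaction`, `n_subjects`, `n_groups`,
#'   `df_error`, `degenerate`.
#' @export
rm_anova_two_timepoints <- function(baseline, followup, group_labels = NULL) {
  if (length(baseline) != length(followup)) {
    abort("`baseline` and `followup` must have the same length.")
  }
  has_groups <- !is.null(group_labels)
  if (has_groups && length(group_labels) != length(baseline)) {
    abort("`group_labels` must align with the measurements.")
  }
  keep <- complete.cases(baseline, followup,
                         if (has_groups) group_labels else NULL)
  baseline <- baseline[keep]
  followup <- followup[keep]
  n <- length(baseline)
  if (n < 3) abort("At least 3 complete pairs are required.")

  d <- followup - baseline
  degenerate <- var(baseline) == 0 && var(followup) == 0

  if (has_groups) {
    g <- droplevels(factor(group_labels[keep]))
    sizes <- table(g)
    if (any(sizes < 2)) {
      abort(paste0(
        "Every group needs at least 2 members; singleton group(s): ",
        paste(names(sizes)[sizes < 2], collapse = ", ")
      ))
    }
    k <- nlevels(g)
  } else {
    g <- factor(rep("all", n))
    k <- 1L
  }

  group_means <- tapply(d, g, mean)
  n_h <- k / sum(1 / table(g))            # harmonic mean of group sizes
  u <- mean(group_means)                  # unweighted grand mean of change
  # Sums of squares on the normalized within-subject contrast d / sqrt(2):
  ss_time <- k * n_h * u^2 / 2
  ss_interaction <- if (k > 1) n_h * sum((group_means - u)^2) / 2 else 0
  ss_error <- sum((d - group_means[g])^2) / 2
  df_error <- n - k

  f_of <- function(ss, df1) {
    if (ss_error == 0) {
      if (ss == 0) 0 else Inf
    } else {
      (ss / df1) / (ss_error / df_error)
    }
  }
  eta_of <- function(ss) {
    denom <- ss + ss_error
    if (denom == 0) 0 else ss / denom
  }

  f_time <- f_of(ss_time, 1)
  p_time <- pf(f_time, 1, df_error, lower.tail = FALSE)
  if (k > 1) {
    f_int <- f_of(ss_interaction, k - 1)
    p_int <- pf(f_int, k - 1, df_error, lower.tail = FALSE)
  } else {
    f_int <- 0
    p_int <- NA_real_
  }

  structure(
    list(
      ss_time = ss_time,
      ss_interaction = ss_interaction,
      ss_within_error = ss_error,
      f_time = f_time,
      f_interaction = f_int,
      p_time = p_time,
      p_interaction = p_int,
      eta2_time = if (degenerate) 0 else eta_of(ss_time),
      eta2_interaction = if (degenerate) 0 else eta_of(ss_interaction),
      n_subjects = n,
      n_groups = k,
      df_error = df_error,
      degenerate = degenerate
    ),
    class = "rm_anova_result"
  )
}

#' @export
print.rm_anova_result <- function(x, ...) {
  cat(sprintf("time: F(1, %d) = %.3f, p = %.4g, eta2 = %.4f\n",
              x$df_error, x$f_time, x$p_time, x$eta2_time))
  if (x$n_groups > 1) {
    cat(sprintf("group x time: F(%d, %d) = %.3f, p = %.4g, eta2 = %.4f\n",
                x$n_groups - 1, x$df_error, x$f_interaction,
                x$p_interaction, x$eta2_interaction))
  }
  if (x$degenerate) cat("degenerate fit: zero variance at both timepoints\n")
  invisible(x)
}

#' Descriptive summary with skewness-driven style
#'
#' Summarizes a measurement the way skewed biomedical data are reported:
#' median (interquartile range) when the absolute sample skewness exceeds
#' `skew_threshold`, mean (standard deviation) otherwise. Skewness uses the
#' adjusted (SPSS/SAS-style) estimator; quartiles use linear interpolation
#' between order statistics (`stats::quantile` type 7).
#'
#' @param values Numeric vector; missing values are dropped.
#' @param skew_threshold Absolute-skewness cutoff for the median/IQR style.
#' @return A `descriptive_summary`: list with `n`, `central`, `spread_low`,
#'   `spread_high`, `sd`, `style` ("median_iqr" or "mean_sd"), `skewness`.
#' @export
#' @examples
#' summarize_measure(c(1, 2, 3, 4, 5))
summarize_measure <- function(values, skew_threshold = 1.0) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2) abort("At least 2 non-missing values are required.")
  skew <- if (n >= 3 && sd(values) > 0) {
    e1071::skewness(values, type = 2)
  } else {
    0
  }
  if (is.finite(skew) && abs(skew) > skew_threshold) {
    q <- unname(quantile(values, c(0.25, 0.5, 0.75), type = 7))
    out <- list(n = n, central = q[2], spread_low = q[1], spread_high = q[3],
                sd = NA_real_, style = "median_iqr", skewness = skew)
  } else {
    out <- list(n = n, central = mean(values), spread_low = NA_real_,
                spread_high = NA_real_, sd = sd(values), style = "mean_sd",
                skewness = skew)
  }
  structure(out, class = "descriptive_summary")
}

#' @export
format.descriptive_summary <- function(x, digits = 1, ...) {
  if (x$style == "median_iqr") {
    sprintf("%.*f (%.*f to %.*f)", digits, x$central, digits, x$spread_low,
            digits, x$spread_high)
  } else {
    sprintf("%.*f (%.*f)", digits, x$central, digits, x$sd)
  }
}

#' @export
print.descriptive_summary <- function(x, ...) {
  cat(format(x), sprintf("[n = %d, %s]\n", x$n, x$style))
  invisible(x)
}
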