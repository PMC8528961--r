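# Cohort-level association statistics: correlation, linear models with
# batch adjustment, two-group tests, the sequential-covariate model ladder,
# the cohort characteristics table, and ratio summaries.

#' Pearson correlation with t-based p-value
#'
#' @param x,y Finite numeric vectors of equal length, n >= 3.
#' @return List with `r`, `r_squared`, `p` (two-sided, t-distribution with
#'   n - 2 df) and `n`.
#' @export
correlate <- function(x, y) {
  assert_finite(x, "x"); assert_finite(y, "y")
  if (length(x) != length(y) || length(x) < 3) {
    mc_abort("correlate needs equal-length vectors with n >= 3",
             "methclock_validation_error")
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    mc_abort("zero variance in x or y", "methclock_degenerate_error")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), r_squared = unname(ct$estimate)^2,
       p = ct$p.value, n = length(x))
}

# Coerce a covariate column for model fitting; categoricals get alphabetical
# reference levels.
as_covariate <- function(x) {
  if (is.numeric(x)) return(x)
  if (is.logical(x)) return(factor(x, levels = c(FALSE, TRUE)))
  factor(as.character(x), levels = sort(unique(as.character(x))))
}

#' Ordinary least-squares fit with Wald confidence intervals
#'
#' Categorical covariates are dummy-encoded with the alphabetically first
#' level as reference. Rank deficiency is an error naming the aliased
#' columns (no silent dropping).
#'
#' @param response Numeric response vector.
#' @param covariates Data.frame (or named list) of covariates.
#' @param conf_level Confidence level (default 0.95).
#' @return A `regression_fit`: list with `coefficients` (data.frame of term,
#'   estimate, ci_lo, ci_hi, p), `rss`, `n`, `covariates` and the underlying
#'   `lm` fit in `$fit`.
#' @export
fit_linear <- function(response, covariates, conf_level = 0.95) {
  assert_finite(response, "response")
  covariates <- as.data.frame(covariates, stringsAsFactors = FALSE)
  if (nrow(covariates) != length(response)) {
    mc_abort("covariate rows must match response length",
             "methclock_validation_error")
  }
  df <- as.data.frame(lapply(covariates, as_covariate))
  df$.response <- response
  fit <- stats::lm(.response ~ ., data = df)
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    mc_abort(sprintf("rank-deficient design; aliased: %s",
                     paste(names(cf)[is.na(cf)], collapse = ", ")),
             "methclock_collinearity_error")
  }
  ci <- stats::confint(fit, level = conf_level)
  sm <- summary(fit)$coefficients
  coefs <- data.frame(term = names(cf), estimate = unname(cf),
                      ci_lo = ci[, 1], ci_hi = ci[, 2],
                      p = sm[names(cf), "Pr(>|t|)"],
                      row.names = NULL, stringsAsFactors = FALSE)
  structure(list(coefficients = coefs,
                 rss = sum(stats::residuals(fit)^2),
                 n = length(response),
                 covariates = names(covariates),
                 fit = fit),
            class = "regression_fit")
}

#' Two-group test (Mann-Whitney, t, or paired signed-rank)
#'
#' In Mann-Whitney mode the p-value is exact for combined n <= 20 without
#' ties, otherwise a normal approximation with tie correction; always
#' two-sided. `mode = "auto"` selects the paired signed-rank test when
#' `pair_id` is supplied and Mann-Whitney otherwise.
#'
#' @param values Numeric vector.
#' @param group Two-level grouping vector.
#' @param mode One of `"auto"`, `"mann_whitney"`, `"t"`,
#'   `"wilcoxon_paired"`.
#' @param pair_id Pair identifiers for the paired mode; every id must occur
#'   exactly once in each group.
#' @return List with `statistic`, `p` and `method`.
#' @export
two_group_test <- function(values, group,
                           mode = c("auto", "mann_whitney", "t",
                                    "wilcoxon_paired"),
                           pair_id = NULL) {
  mode <- match.arg(mode)
  group <- as_covariate(group)
  if (nlevels(group) != 2) {
    mc_abort("group must have exactly two levels",
             "methclock_validation_error")
  }
  g1 <- values[group == levels(group)[1]]
  g2 <- values[group == levels(group)[2]]
  if (length(g1) < 2 || length(g2) < 2) {
    mc_abort("need at least two observations per group",
             "methclock_validation_error")
  }
  if (mode == "auto") {
    mode <- if (is.null(pair_id)) "mann_whitney" else "wilcoxon_paired"
  }
  if (mode == "mann_whitney") {
    if (length(unique(values)) == 1L) {
      # every observation tied: no evidence either way
      return(list(statistic = length(g1) * length(g2) / 2, p = 1,
                  method = "mann_whitney"))
    }
    exact <- (length(g1) + length(g2) <= 20) && !anyDuplicated(values)
    ht <- suppressWarnings(
      stats::wilcox.test(g1, g2, exact = exact, correct = !exact))
    list(statistic = unname(ht$statistic), p = ht$p.value,
         method = "mann_whitney")
  } else if (mode == "t") {
    ht <- stats::t.test(g1, g2)
    list(statistic = unname(ht$statistic), p = ht$p.value, method = "t")
  } else {
    if (is.null(pair_id)) {
      mc_abort("paired mode requires pair_id", "methclock_pairing_error")
    }
    id1 <- pair_id[group == levels(group)[1]]
    id2 <- pair_id[group == levels(group)[2]]
    if (length(id1) != length(id2) || anyDuplicated(id1) ||
        anyDuplicated(id2) || !setequal(id1, id2)) {
      mc_abort("pair_id does not define complete 1:1 pairs",
               "methclock_pairing_error")
    }
    d <- g1[order(id1)] - g2[order(id2)]
    if (all(d == 0)) {
      return(list(statistic = 0, p = 1, method = "wilcoxon_paired"))
    }
    ht <- suppressWarnings(stats::wilcox.test(d))
    list(statistic = unname(ht$statistic), p = ht$p.value,
         method = "wilcoxon_paired")
  }
}

ladder_covariates <- list(
  model0 = character(0),
  model1 = "donor_age",
  model2 = c("donor_sex", "donor_bmi", "cmv_group", "donor_white"),
  model3 = c("recipient_age", "recipient_sex", "recipient_bmi",
             "recipient_white", "indication"))

#' Sequential nested regression models of methylation age on PGD
#'
#' Fits the four nested models of methylation age: (0) PGD + batch;
#' (1) + donor age; (2) + donor sex, donor BMI, CMV group, donor White
#' ethnicity; (3) + recipient age, sex, BMI, White ethnicity and transplant
#' indication. Batch enters every model as a fixed-effect covariate,
#' including the "unadjusted" model. Successive models are compared by
#' ANOVA F-tests.
#'
#' @param table A [sample_table] carrying all ladder covariates, complete
#'   (no missing values; missingness is an error, never silently dropped).
#' @param meth_age Methylation-age vector, one per row of `table`.
#' @return A `model_ladder`: list with `fits` (list of `regression_fit`),
#'   `anova_p` (NA then three successive F-test p-values), `improved`
#'   (logical at alpha = 0.05) and `table`, a report with one row per model
#'   (RSS, PGD estimate, CI, p-value, ANOVA p).
#' @export
sequential_models <- function(table, meth_age) {
  needed <- unique(c("pgd", "batch", unlist(ladder_covariates)))
  missing_cols <- setdiff(needed, names(table))
  if (length(missing_cols)) {
    mc_abort(sprintf("sample table lacks ladder covariate(s): %s",
                     paste(missing_cols, collapse = ", ")),
             "methclock_schema_error")
  }
  if (anyNA(table[needed])) {
    mc_abort("missing covariate values; the model ladder does not impute",
             "methclock_validation_error")
  }
  if (length(meth_age) != nrow(table)) {
    mc_abort("meth_age length must match sample table",
             "methclock_validation_error")
  }
  fits <- list()
  cum <- c("pgd", "batch")
  for (m in names(ladder_covariates)) {
    cum <- unique(c(cum, ladder_covariates[[m]]))
    fits[[m]] <- fit_linear(meth_age, table[cum])
  }
  anova_p <- rep(NA_real_, length(fits))
  for (i in seq_along(fits)[-1]) {
    a <- stats::anova(fits[[i - 1]]$fit, fits[[i]]$fit)
    anova_p[i] <- a$`Pr(>F)`[2]
  }
  pgd_rows <- lapply(fits, function(f) {
    f$coefficients[f$coefficients$term == "pgdTRUE", ]
  })
  report <- data.frame(
    model = names(fits),
    rss = vapply(fits, `[[`, numeric(1), "rss"),
    pgd_estimate = vapply(pgd_rows, `[[`, numeric(1), "estimate"),
    pgd_ci_lo = vapply(pgd_rows, `[[`, numeric(1), "ci_lo"),
    pgd_ci_hi = vapply(pgd_rows, `[[`, numeric(1), "ci_hi"),
    pgd_p = vapply(pgd_rows, `[[`, numeric(1), "p"),
    anova_p = anova_p,
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(fits = fits, anova_p = anova_p,
                 improved = !is.na(anova_p) & anova_p < 0.05,
                 table = report),
            class = "model_ladder")
}

summarize_continuous <- function(x, normal) {
  if (normal) {
    sprintf("%.1f (%.1f)", mean(x), stats::sd(x))
  } else {
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7)
    sprintf("%.1f [%.1f, %.1f]", q[2], q[1], q[3])
  }
}

summarize_categorical <- function(x, level) {
  n <- sum(x == level)
  sprintf("%d (%.0f%%)", n, 100 * n / length(x))
}

#' Cohort characteristics table
#'
#' For each variable, continuous values are routed by Shapiro-Wilk normality
#' (alpha = 0.05, either group non-normal routes to the nonparametric arm):
#' normal variables are summarized as mean (SD) and compared by Student's
#' t-test; non-normal as median \[IQR\] compared by Mann-Whitney.
#' Categorical variables are summarized as N (%) and compared by chi-squared
#' (Yates continuity correction for 2x2 tables only). Single-level
#' categoricals are reported without a test. No multiplicity adjustment is
#' applied across rows.
#'
#' @param table A [sample_table] (or data.frame).
#' @param group Name of a two-level grouping column (default `"pgd"`).
#' @param variables Columns to summarize; defaults to all columns except
#'   the group, sample ids and the survival triple.
#' @return A data.frame of class `cohort_table` with one row per variable
#'   (categoricals expand to one row per level for display) and columns
#'   `variable`, `level`, per-group summaries, `test`, `p`, `normal`.
#' @export
cohort_table <- function(table, group = "pgd", variables = NULL) {
  df <- as.data.frame(table)
  if (!group %in% names(df)) {
    mc_abort(sprintf("grouping column '%s' absent", group),
             "methclock_schema_error")
  }
  g <- as_covariate(df[[group]])
  if (nlevels(g) != 2 || min(table(g)) < 2) {
    mc_abort("need two groups with >= 2 subjects each",
             "methclock_validation_error")
  }
  variables <- variables %||% setdiff(
    names(df), c(group, "sample_id", "entry_time", "event_time", "event"))
  rows <- list()
  for (v in variables) {
    x <- df[[v]]
    if (is.numeric(x)) {
      sw_p <- vapply(levels(g), function(l) {
        xs <- x[g == l]
        if (length(unique(xs)) < 3) return(0)
        stats::shapiro.test(xs)$p.value
      }, numeric(1))
      normal <- all(sw_p >= 0.05)
      tt <- two_group_test(x, g, mode = if (normal) "t" else "mann_whitney")
      rows[[length(rows) + 1]] <- data.frame(
        variable = v, level = NA_character_,
        group1 = summarize_continuous(x[g == levels(g)[1]], normal),
        group2 = summarize_continuous(x[g == levels(g)[2]], normal),
        test = if (normal) "t" else "mann_whitney",
        p = tt$p, normal = normal, stringsAsFactors = FALSE)
    } else {
      xf <- as_covariate(x)
      tab <- table(xf, g)
      if (nlevels(xf) < 2) {
        test <- "none"; p <- NA_real_
      } else {
        test <- "chi_squared"
        p <- suppressWarnings(stats::chisq.test(
          tab, correct = nlevels(xf) == 2)$p.value)
      }
      for (l in levels(xf)) {
        rows[[length(rows) + 1]] <- data.frame(
          variable = v, level = l,
          group1 = summarize_categorical(xf[g == levels(g)[1]], l),
          group2 = summarize_categorical(xf[g == levels(g)[2]], l),
          test = test, p = p, normal = NA, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  names(out)[names(out) == "group1"] <- paste0(group, "=", levels(g)[1])
  names(out)[names(out) == "group2"] <- paste0(group, "=", levels(g)[2])
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Ratio of methylation age to graft age
#'
#' @param meth_age Methylation ages (years).
#' @param graft_age Graft chronologic ages (years, strictly positive).
#' @return List with `median`, `q1`, `q3` (type-7 linear-interpolation
#'   quantiles) and the elementwise `ratios`.
#' @export
ratio_summary <- function(meth_age, graft_age) {
  assert_finite(meth_age, "meth_age"); assert_finite(graft_age, "graft_age")
  if (length(meth_age) != length(graft_age)) {
    mc_abort("vectors must have equal length", "methclock_validation_error")
  }
  if (any(graft_age <= 0)) {
    mc_abort("graft_age must be strictly positive", "methclock_domain_error")
  }
  r <- meth_age / graft_age
  q <- stats::quantile(r, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  list(median = q[2], q1 = q[1], q3 = q[3], ratios = r)
}
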