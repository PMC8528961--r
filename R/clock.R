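# The epigenetic clock: calibrated age transform, penalized training,
# and per-sample age prediction from beta matrices.

#' Calibrated age transform
#'
#' Piecewise log/linear calibration used by multi-tissue epigenetic clocks:
#' logarithmic below the `adult_age` anchor (where methylation change is
#' fast) and linear above it,
#' `F(a) = log(a + 1) - log(adult_age + 1)` for `a <= adult_age`, else
#' `(a - adult_age) / (adult_age + 1)`. `F` is continuous, strictly
#' increasing, and satisfies `F(adult_age) = 0`.
#'
#' @param age Age(s) in years; must exceed -1.
#' @param adult_age Calibration anchor in years (default 20).
#' @return Transformed age(s), dimensionless.
#' @seealso [inverse_transform_age]
#' @export
transform_age <- function(age, adult_age = 20) {
  if (!is_scalar_number(adult_age) || adult_age <= 0) {
    mc_abort("adult_age must be a positive number", "methclock_domain_error")
  }
  if (any(!is.finite(age)) || any(age <= -1)) {
    mc_abort("age must be finite and greater than -1",
             "methclock_domain_error")
  }
  ifelse(age <= adult_age,
         log(age + 1) - log(adult_age + 1),
         (age - adult_age) / (adult_age + 1))
}

#' Inverse of the calibrated age transform
#'
#' @param x Transformed age(s).
#' @param adult_age Calibration anchor in years.
#' @return Age(s) in years; exact inverse of [transform_age].
#' @export
inverse_transform_age <- function(x, adult_age = 20) {
  if (!is_scalar_number(adult_age) || adult_age <= 0) {
    mc_abort("adult_age must be a positive number", "methclock_domain_error")
  }
  if (any(!is.finite(x))) {
    mc_abort("transformed age must be finite", "methclock_domain_error")
  }
  ifelse(x <= 0,
         exp(x + log(adult_age + 1)) - 1,
         x * (adult_age + 1) + adult_age)
}

#' Train an epigenetic clock by elastic-net regression
#'
#' Fits transformed age `F(age)` against CpG betas with an elastic-net
#' penalty (via glmnet). Penalty strength is chosen by seeded k-fold
#' cross-validation; ties are broken toward the stronger penalty (the
#' "1-SE" rule) unless `penalty = "cv.min"` or a numeric penalty is given.
#' Handles p > n. Only CpGs with nonzero weight enter the returned model,
#' together with their training mean betas (for imputation at prediction).
#'
#' @param betas A [beta_matrix] of training samples.
#' @param ages Chronologic ages (years), one per sample.
#' @param adult_age Age-transform anchor (years).
#' @param alpha Elastic-net mixing parameter in \[0, 1\] (default 0.5).
#' @param penalty `"cv.1se"` (default), `"cv.min"`, or a numeric lambda.
#' @param nfolds Cross-validation folds (default 10).
#' @param seed Integer seed for the fold assignment.
#' @return A [clock_model]; `training_meta$n_nonzero` reports the count of
#'   CpGs retained with nonzero weight.
#' @export
train_clock <- function(betas, ages, adult_age = 20, alpha = 0.5,
                        penalty = "cv.1se", nfolds = 10, seed = 1) {
  x <- unclass(betas)
  if (nrow(x) < 10) {
    mc_abort("clock training requires at least 10 samples",
             "methclock_validation_error")
  }
  if (length(ages) != nrow(x)) {
    mc_abort("length(ages) must equal the number of samples",
             "methclock_validation_error")
  }
  assert_finite(ages, "ages")
  if (stats::var(ages) == 0) {
    mc_abort("ages are constant: degenerate response",
             "methclock_degenerate_error")
  }
  y <- transform_age(ages, adult_age)
  if (is.numeric(penalty)) {
    # extend the default path down to the requested penalty so glmnet's
    # warm starts converge, then read coefficients at that penalty
    fit0 <- glmnet::glmnet(x, y, alpha = alpha)
    lmax <- max(fit0$lambda)
    lam <- max(penalty, 1e-10)
    path <- exp(seq(log(lmax), log(min(lam, lmax)), length.out = 100))
    fit <- glmnet::glmnet(x, y, alpha = alpha, lambda = path)
    cf <- as.numeric(stats::coef(fit, s = lam))
    lambda_used <- lam
  } else {
    penalty <- match.arg(penalty, c("cv.1se", "cv.min"))
    nfolds <- max(3L, min(nfolds, floor(nrow(x) / 3)))  # >=3 obs per fold
    foldid <- withr::with_seed(seed,
      sample(rep_len(seq_len(nfolds), nrow(x))))
    cvfit <- glmnet::cv.glmnet(x, y, alpha = alpha, foldid = foldid)
    lambda_used <- if (penalty == "cv.1se") cvfit$lambda.1se else
      cvfit$lambda.min
    cf <- as.numeric(stats::coef(cvfit, s = lambda_used))
  }
  intercept <- cf[1]
  w <- cf[-1]
  keep <- which(w != 0)
  clock_model(
    cpg_ids = colnames(x)[keep],
    weights = w[keep],
    intercept = intercept,
    adult_age = adult_age,
    training_means = colMeans(x[, keep, drop = FALSE], na.rm = TRUE),
    training_meta = list(n_train = nrow(x), alpha = alpha,
                         lambda = lambda_used, n_nonzero = length(keep)))
}

#' Predict epigenetic age from a beta matrix
#'
#' Computes `inverse_transform(intercept + sum(weights * beta))` per sample.
#' Model CpGs absent from `betas` (or missing within a sample) are imputed
#' with their stored training means; a warning reports the imputed fraction.
#' Prediction is per-sample, so batch-subset and pooled predictions are
#' identical, and it is invariant to CpG column order.
#'
#' @param model A [clock_model].
#' @param betas A [beta_matrix].
#' @param min_overlap Minimum fraction of model CpGs that must be present
#'   (default 0.9).
#' @return Named numeric vector of predicted ages (years), in sample order.
#' @export
predict_age <- function(model, betas, min_overlap = 0.9) {
  x <- unclass(betas)
  present <- intersect(model$cpg_ids, colnames(x))
  frac <- if (length(model$cpg_ids) == 0) 1 else
    length(present) / length(model$cpg_ids)
  if (frac < min_overlap) {
    missing_cpgs <- setdiff(model$cpg_ids, colnames(x))
    mc_abort(sprintf(
      "only %.1f%% of model CpGs present (threshold %.1f%%); missing: %s",
      100 * frac, 100 * min_overlap,
      paste(utils::head(missing_cpgs, 10), collapse = ", ")),
      "methclock_coverage_error")
  }
  xm <- matrix(NA_real_, nrow = nrow(x), ncol = length(model$cpg_ids),
               dimnames = list(rownames(x), model$cpg_ids))
  xm[, present] <- x[, present, drop = FALSE]
  n_imputed <- sum(is.na(xm))
  if (n_imputed > 0) {
    if (is.null(model$training_means)) {
      mc_abort("model has no stored training means; cannot impute",
               "methclock_coverage_error")
    }
    for (j in which(colSums(is.na(xm)) > 0)) {
      xm[is.na(xm[, j]), j] <- model$training_means[j]
    }
    mc_warn(sprintf("imputed %.2f%% of model-CpG values with training means",
                    100 * n_imputed / length(xm)),
            "methclock_imputation_warning")
  }
  score <- drop(xm %*% model$weights) + model$intercept
  stats::setNames(inverse_transform_age(score, model$adult_age), rownames(x))
}
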