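test_that("correlation matches closed form and degenerates are typed errors", {
  r <- correlate(c(0, 1, 2), c(0, 2, 4) + 1)
  expect_equal(r$r, 1)
  expect_equal(r$r_squared, 1)

  r2 <- correlate(c(0, 1, 2), c(0, 1, 3))
  expect_equal(r2$r, 3 / sqrt(2 * 14 / 3), tolerance = 1e-10)
  expect_equal(round(r2$r, 4), 0.982)

  expect_error(correlate(c(1, 1, 1), c(0, 1, 2)),
               class = "methclock_degenerate_error")
})

test_that("correlation p-values are uniform under the null", {
  ps <- withr::with_seed(17, vapply(1:1000, function(i) {
    correlate(rnorm(15), rnorm(15))$p
  }, numeric(1)))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("OLS matches the normal-equation oracle on random designs", {
  withr::with_seed(23, {
    for (i in 1:20) {
      n <- sample(8:25, 1)
      X <- cbind(1, matrix(rnorm(n * 3), n, 3))
      y <- rnorm(n)
      fit <- fit_linear(y, data.frame(x1 = X[, 2], x2 = X[, 3], x3 = X[, 4]))
      beta_hat <- solve(crossprod(X), crossprod(X, y))
      expect_equal(fit$coefficients$estimate, drop(beta_hat),
                   tolerance = 1e-10, ignore_attr = TRUE)
    }
  })
  # closed-form 3-point example
  fit <- fit_linear(c(0, 1, 3), data.frame(x = c(0, 1, 2)))
  expect_equal(fit$coefficients$estimate, c(-1 / 6, 1.5), tolerance = 1e-12)
})

test_that("rank-deficient designs raise a collinearity error naming columns", {
  d <- data.frame(a = 1:6, b = (1:6) * 2)
  expect_error(fit_linear(rnorm(6), d), "b",
               class = "methclock_collinearity_error")
})

test_that("two-group tests match spec contracts", {
  mw <- two_group_test(c(1, 2, 3, 4), c("x", "x", "y", "y"))
  expect_equal(mw$p, 1 / 3, tolerance = 1e-12)

  tied <- two_group_test(rep(5, 6), rep(c("x", "y"), each = 3))
  expect_equal(tied$p, 1)

  paired0 <- two_group_test(c(1, 2, 3, 1, 2, 3),
                            rep(c("a", "b"), each = 3),
                            mode = "wilcoxon_paired",
                            pair_id = c(1, 2, 3, 1, 2, 3))
  expect_equal(paired0$p, 1)

  expect_error(
    two_group_test(1:4, rep(c("a", "b"), each = 2),
                   mode = "wilcoxon_paired", pair_id = c(1, 2, 1, 3)),
    class = "methclock_pairing_error")
})

test_that("model ladder is nested, batch-adjusted, and reports Table-2 shape", {
  sim <- simulate_cohort(sim_config(seed = 61))
  meth <- sim$truth$apparent_age
  ml <- sequential_models(sim$samples, meth)
  expect_named(ml$fits, c("model0", "model1", "model2", "model3"))
  expect_true(all(diff(ml$table$rss) <= 1e-9))
  expect_true(all(vapply(ml$fits, function(f) {
    any(grepl("^batch", f$coefficients$term))
  }, logical(1))))
  expect_true(all(ml$table$pgd_ci_lo <= ml$table$pgd_estimate &
                    ml$table$pgd_estimate <= ml$table$pgd_ci_hi))

  no_cov <- sim$samples
  expect_error(sequential_models(no_cov[setdiff(names(no_cov), "donor_bmi")],
                                 meth),
               class = "methclock_schema_error")
})

test_that("donor-age confounding attenuates the PGD coefficient down the
           ladder", {
  withr::with_seed(71, {
    n <- 60
    donor_age <- runif(n, 20, 65)
    # cases drawn preferentially from older donors
    pgd <- runif(n) < plogis((donor_age - 42) / 6)
    meth <- 0.5 * donor_age + 3 * pgd + rnorm(n, 0, 3)
    tab <- sample_table(data.frame(
      sample_id = sprintf("s%02d", 1:n), donor_age = donor_age,
      recipient_age = runif(n, 25, 70), pgd = pgd,
      batch = rep(c("B1", "B2"), length.out = n),
      donor_sex = sample(c("M", "F"), n, TRUE),
      recipient_sex = sample(c("M", "F"), n, TRUE),
      donor_bmi = rnorm(n, 25, 3), recipient_bmi = rnorm(n, 26, 4),
      donor_white = runif(n) < 0.5, recipient_white = runif(n) < 0.6,
      cmv_group = sample(c("D-R-", "D+R+"), n, TRUE),
      indication = sample(c("A", "D"), n, TRUE),
      entry_time = 365, event_time = 1000, event = FALSE))
    ml <- sequential_models(tab, meth)
    expect_gt(ml$table$pgd_estimate[1], ml$table$pgd_estimate[2])
  })
})

test_that("cohort table routes variables by normality and type", {
  route <- function(gen, seeds = 1:20) {
    vapply(seeds, function(s) {
      withr::with_seed(s, {
        x <- gen(30)
        g <- rep(c(TRUE, FALSE), 15)
        tab <- data.frame(pgd = g, v = x)
        ct <- cohort_table(tab, group = "pgd", variables = "v")
        ct$test[1]
      })
    }, character(1))
  }
  normal_routes <- route(function(n) rnorm(n))
  expect_gte(mean(normal_routes == "t"), 0.9)
  skewed_routes <- route(function(n) exp(rnorm(n, 0, 1.2)))
  expect_gt(mean(skewed_routes == "mann_whitney"), 0.5)

  counts <- data.frame(
    pgd = rep(c(FALSE, TRUE), c(15, 13)),
    cat = c(rep("yes", 6), rep("no", 9), rep("yes", 9), rep("no", 4)))
  ct <- cohort_table(counts, group = "pgd", variables = "cat")
  expect_equal(unique(ct$test), "chi_squared")
  expect_gt(ct$p[1], 0.05)

  single <- data.frame(pgd = rep(c(TRUE, FALSE), 5), only = "same")
  ct2 <- cohort_table(single, group = "pgd", variables = "only")
  expect_equal(unique(ct2$test), "none")
  expect_true(all(is.na(ct2$p)))
})

test_that("ratio summary uses type-7 quantiles and guards zero graft age", {
  rs <- ratio_summary(c(10, 20, 30), c(10, 20, 30))
  expect_equal(rs$median, 1)
  expect_equal(rs$q3 - rs$q1, 0)

  rs2 <- ratio_summary(c(0.2, 0.4, 0.6), c(1, 1, 1))
  expect_equal(rs2$median, 0.4)

  expect_error(ratio_summary(1, 0), class = "methclock_domain_error")
})
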