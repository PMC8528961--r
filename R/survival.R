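# Left-truncated survival analysis: Cox models of CLAD-or-death, tertile
# coding, Kaplan-Meier curves with delayed entry, and simulation-based
# power for a per-unit hazard ratio.

#' Left-truncated Cox proportional-hazards fit
#'
#' Maximizes the partial likelihood with risk sets restricted to
#' `entry_time < t <= event_time` (delayed entry at the airway brush) and
#' Efron handling of ties; Wald confidence intervals. A constant predictor
#' carries no information and is returned as HR exactly 1 with p = 1.
#'
#' @param table A [sample_table] with the survival triple.
#' @param predictor Numeric vector or factor (e.g. tertile codes), one per
#'   subject.
#' @param adjust_batch Include batch as a fixed-effect covariate
#'   (default TRUE; ignored when the table has a single batch level).
#' @return A `cox_fit`: list with `coefficients` (data.frame of term, coef,
#'   hr, ci_lo, ci_hi, p), `n`, `n_events`, `ties`, `converged` and the
#'   underlying `coxph` fit (`$fit`, NULL for the constant-predictor case).
#' @export
fit_cox <- function(table, predictor, adjust_batch = TRUE) {
  if (length(predictor) != nrow(table)) {
    mc_abort("predictor length must match sample table",
             "methclock_validation_error")
  }
  if (sum(table$event) < 1) {
    mc_abort("no events observed; cannot fit Cox model",
             "methclock_validation_error")
  }
  if (length(unique(predictor)) == 1L) {
    coefs <- data.frame(term = "predictor", coef = 0, hr = 1,
                        ci_lo = NA_real_, ci_hi = NA_real_, p = 1,
                        stringsAsFactors = FALSE)
    return(structure(list(coefficients = coefs, n = nrow(table),
                          n_events = sum(table$event), ties = "efron",
                          converged = TRUE, fit = NULL),
                     class = "cox_fit"))
  }
  df <- data.frame(entry = table$entry_time, time = table$event_time,
                   event = table$event,
                   predictor = if (is.numeric(predictor)) predictor else
                     as_covariate(predictor))
  form <- survival::Surv(entry, time, event) ~ predictor
  if (adjust_batch && length(unique(table$batch)) > 1) {
    df$batch <- as_covariate(table$batch)
    form <- survival::Surv(entry, time, event) ~ predictor + batch
  }
  converged <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(form, data = df, ties = "efron"),
    warning = function(w) {
      if (grepl("infinite|converge|beta may be", conditionMessage(w))) {
        converged <<- FALSE
        invokeRestart("muffleWarning")
      }
    })
  sm <- summary(fit)
  cf <- sm$coefficients
  ci <- sm$conf.int
  coefs <- data.frame(term = rownames(cf), coef = cf[, "coef"],
                      hr = exp(cf[, "coef"]),
                      ci_lo = ci[, "lower .95"], ci_hi = ci[, "upper .95"],
                      p = cf[, "Pr(>|z|)"],
                      row.names = NULL, stringsAsFactors = FALSE)
  if (!converged) {
    mc_warn(sprintf(
      "monotone likelihood suspected (direction: %s); estimates unreliable",
      paste(ifelse(cf[, "coef"] > 0, "+", "-"), collapse = "")),
      "methclock_separation_warning")
  }
  structure(list(coefficients = coefs, n = nrow(df),
                 n_events = sum(df$event), ties = "efron",
                 converged = converged, fit = fit),
            class = "cox_fit")
}

#' Assign tertiles
#'
#' Cutpoints at the 33.3rd and 66.7th percentiles (type-7 quantiles); values
#' tied with a cutpoint fall in the lower tertile. With distinct values the
#' group sizes differ by at most one.
#'
#' @param values Numeric vector, n >= 3.
#' @return Integer vector of tertile codes 1-3.
#' @export
tertile_assign <- function(values) {
  assert_finite(values, "values")
  if (length(values) < 3) {
    mc_abort("tertile assignment needs n >= 3", "methclock_validation_error")
  }
  if (length(unique(values)) < 3) {
    mc_warn("fewer than 3 distinct values: degenerate tertiles",
            "methclock_degenerate_warning")
    return(rep(1L, length(values)))
  }
  q <- stats::quantile(values, c(1, 2) / 3, type = 7, names = FALSE)
  ifelse(values <= q[1], 1L, ifelse(values <= q[2], 2L, 3L))
}

#' Kaplan-Meier curves with delayed entry
#'
#' Left-truncation-aware product-limit estimates per stratum, as a stepwise
#' table suitable for plotting.
#'
#' @param table A [sample_table].
#' @param strata Optional stratification vector (e.g. tertiles); `NULL` for
#'   a single curve. Empty strata are dropped with a warning.
#' @return Data.frame of class `km_curve` with columns `stratum`, `time`,
#'   `n_risk`, `n_event`, `surv`.
#' @export
km_curve <- function(table, strata = NULL) {
  df <- data.frame(entry = table$entry_time, time = table$event_time,
                   event = table$event)
  if (is.null(strata)) {
    df$stratum <- factor("all")
  } else {
    if (length(strata) != nrow(table)) {
      mc_abort("strata length must match sample table",
               "methclock_validation_error")
    }
    s <- if (is.factor(strata)) strata else as_covariate(strata)
    empty <- setdiff(levels(s), unique(as.character(s)))
    if (length(empty)) {
      mc_warn(sprintf("empty stratum(um/a) omitted: %s",
                      paste(empty, collapse = ", ")),
              "methclock_empty_stratum_warning")
      s <- droplevels(s)
    }
    df$stratum <- s
  }
  out <- do.call(rbind, lapply(levels(df$stratum), function(l) {
    sub <- df[df$stratum == l, ]
    sf <- survival::survfit(
      survival::Surv(entry, time, event) ~ 1, data = sub)
    data.frame(stratum = l, time = sf$time, n_risk = sf$n.risk,
               n_event = sf$n.event, surv = sf$surv,
               stringsAsFactors = FALSE)
  }))
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Simulation-based power for a Cox per-unit hazard ratio
#'
#' Emulates a design-stage power analysis on the observed follow-up
#' structure: for each hazard ratio `h` on the grid, predictor values are
#' redrawn from a normal with the observed predictor moments, event times
#' are simulated from a proportional-hazards model whose baseline cumulative
#' hazard is the Nelson-Aalen estimate of the observed data (conditional on
#' each subject's observed entry time), censoring is at each subject's
#' observed follow-up end, and the left-truncated Cox model is refit. The
#' indicator of p < `alpha` is pooled over the grid and a logistic curve of
#' rejection on `h` gives the power at `query_hr`.
#'
#' @param table A [sample_table] with at least one event.
#' @param predictor Observed predictor vector (e.g. methylation age) whose
#'   moments define the simulated predictor distribution.
#' @param hr_grid Hazard ratios (>= 2 values spanning `query_hr`).
#' @param n_sims Simulations per grid point.
#' @param alpha Test size (default 0.05).
#' @param query_hr Hazard ratio at which power is evaluated.
#' @param seed Integer seed.
#' @return A `power_curve`: list with `hr_grid`, `rejection` (per-HR
#'   rejection fraction), `glm_coef`, `power` at `query_hr`, `n_sims`,
#'   `alpha`, `seed`.
#' @export
power_by_simulation <- function(table, predictor, hr_grid, n_sims = 200,
                                alpha = 0.05, query_hr, seed = 1) {
  if (sum(table$event) < 1) {
    mc_abort("no events in observed data; cannot estimate baseline hazard",
             "methclock_validation_error")
  }
  if (length(hr_grid) < 2 || query_hr < min(hr_grid) ||
      query_hr > max(hr_grid)) {
    mc_abort("hr_grid needs >= 2 points spanning query_hr",
             "methclock_validation_error")
  }
  assert_finite(predictor, "predictor")
  mu <- mean(predictor); sdev <- stats::sd(predictor)
  base <- survival::survfit(
    survival::Surv(entry_time, event_time, event) ~ 1,
    data = as.data.frame(table), stype = 2, ctype = 1)  # Nelson-Aalen
  Ht <- base$time; Hv <- base$cumhaz
  entry <- table$entry_time
  fu_end <- table$event_time
  H_entry <- vapply(entry, function(e) {
    i <- findInterval(e, Ht); if (i == 0) 0 else Hv[i]
  }, numeric(1))
  n <- nrow(table)
  res <- withr::with_seed(seed, {
    do.call(rbind, lapply(hr_grid, function(h) {
      reject <- logical(n_sims)
      for (s in seq_len(n_sims)) {
        x <- stats::rnorm(n, mu, sdev)
        lp <- log(h) * (x - mu)
        u <- stats::runif(n)
        target <- H_entry + (-log(u)) / exp(lp)
        T <- vapply(target, function(tg) {
          hit <- which(Hv >= tg)
          if (length(hit)) Ht[hit[1]] else Inf
        }, numeric(1))
        ev <- T <= fu_end
        tm <- pmin(T, fu_end)
        # guard: keep event_time > entry_time by a margin survival's
        # time-merging tolerance cannot collapse (times are in days)
        tm <- pmax(tm, entry + 1e-3)
        sim_tab <- table
        sim_tab$event_time <- tm
        sim_tab$event <- ev
        if (sum(ev) < 2) { reject[s] <- FALSE; next }
        fit <- suppressWarnings(
          fit_cox(sim_tab, x, adjust_batch = FALSE))
        pv <- fit$coefficients$p[fit$coefficients$term == "predictor"]
        reject[s] <- is.finite(pv) && pv < alpha
      }
      data.frame(hr = h, reject = reject)
    }))
  })
  rejection <- tapply(res$reject, res$hr, mean)
  gfit <- suppressWarnings(
    stats::glm(reject ~ hr, data = res, family = stats::binomial()))
  power <- unname(stats::predict(
    gfit, newdata = data.frame(hr = query_hr), type = "response"))
  structure(list(hr_grid = hr_grid,
                 rejection = as.numeric(rejection[as.character(hr_grid)]),
                 glm_coef = stats::coef(gfit),
                 power = power, query_hr = query_hr,
                 n_sims = n_sims, alpha = alpha, seed = seed),
            class = "power_curve")
}
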