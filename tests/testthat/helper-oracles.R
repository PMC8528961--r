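# Independent brute-force oracles used to validate the statistical
# machinery. These deliberately avoid the code paths they check.

# Exact two-sided Mann-Whitney p by full enumeration of group assignments.
# Without ties the U distribution is symmetric, so doubling the smaller
# tail reproduces the exact two-sided p.
mw_enum_p <- function(g1, g2) {
  vals <- c(g1, g2)
  n <- length(vals)
  k <- length(g1)
  u_stat <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  us <- apply(utils::combn(n, k), 2,
              function(idx) u_stat(vals[idx], vals[-idx]))
  u_obs <- u_stat(g1, g2)
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# Benjamini-Hochberg step-up by its definition: q_(i) = min_{j>=i} m p_(j)/j.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  for (i in rev(seq_len(m - 1))) {
    q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1])
  }
  pmin(1, q_sorted)[order(o)]
}

# Two-sample KS statistic by a direct double loop over all evaluation points.
ks_d_oracle <- function(a, b) {
  pts <- c(a, b)
  gaps <- vapply(pts, function(x) {
    abs(mean(a <= x) - mean(b <= x))
  }, numeric(1))
  max(gaps)
}

# Log partial likelihood for untied survival data with optional delayed
# entry, and a grid-search maximizer.
cox_loglik <- function(beta, time, event, x, entry = rep(0, length(time))) {
  ll <- 0
  for (i in which(event)) {
    at_risk <- entry < time[i] & time[i] <= time
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[at_risk])))
  }
  ll
}

cox_grid_beta <- function(time, event, x, entry = rep(0, length(time)),
                          lim = 3, step = 1e-3) {
  grid <- seq(-lim, lim, by = step)
  ll <- vapply(grid, cox_loglik, numeric(1),
               time = time, event = event, x = x, entry = entry)
  grid[which.max(ll)]
}

# Small, fast simulation configuration for unit tests; dots override.
tiny_config <- function(...) {
  args <- list(n_subjects = 20, n_clock_cpgs = 40, n_genes = 60,
               cpgs_per_promoter = 2, n_gene_sets = 10,
               affected_set_names = "HYPOXIA")
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

# Minimal valid sample table for survival tests.
surv_table <- function(entry, time, event, batch = "B1") {
  n <- length(time)
  sample_table(data.frame(
    sample_id = sprintf("s%02d", seq_len(n)),
    donor_age = 40, recipient_age = 50, pgd = FALSE,
    batch = batch, entry_time = entry, event_time = time, event = event))
}
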