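# Promoter-level differential methylation: genome-wide means, CpG-to-
# promoter aggregation, within-batch location normalization, per-promoter
# Welch tests with Benjamini-Hochberg adjustment, and gene-set
# Kolmogorov-Smirnov tests on the t-statistic distribution.

#' Genome-wide mean methylation comparison
#'
#' Per-sample mean beta across all probes, compared between groups by
#' Student's t-test. Samples with no non-missing probes are excluded with a
#' warning. Degenerate case: if neither group varies, p is 1 when the group
#' means agree and 0 when they differ (perfect separation flag).
#'
#' @param betas A [beta_matrix].
#' @param group Two-level grouping vector, one per sample.
#' @return List with `group_means` (named per level), `p` and the
#'   per-sample `sample_means`.
#' @export
global_mean_compare <- function(betas, group) {
  x <- unclass(betas)
  g <- as_covariate(group)
  if (nlevels(g) != 2 || min(table(g)) < 2) {
    mc_abort("need two groups with >= 2 samples each",
             "methclock_validation_error")
  }
  m <- rowMeans(x, na.rm = TRUE)
  dead <- !is.finite(m)
  if (any(dead)) {
    mc_warn(sprintf("excluding %d all-missing sample(s)", sum(dead)),
            "methclock_missing_sample_warning")
    m <- m[!dead]; g <- droplevels(g[!dead])
  }
  m1 <- m[g == levels(g)[1]]; m2 <- m[g == levels(g)[2]]
  if (stats::sd(m1) == 0 && stats::sd(m2) == 0) {
    p <- if (mean(m1) == mean(m2)) 1 else 0
  } else {
    p <- stats::t.test(m1, m2, var.equal = TRUE)$p.value
  }
  list(group_means = stats::setNames(c(mean(m1), mean(m2)), levels(g)),
       p = p, sample_means = m)
}

#' Aggregate CpG betas to promoter methylation
#'
#' Promoter value per sample is the unweighted mean of its CpGs' betas
#' (missing CpGs excluded from the mean). CpGs mapping to no promoter are
#' dropped; a CpG in several overlapping promoters contributes to each.
#'
#' @param betas A [beta_matrix].
#' @param map A [promoter_map].
#' @param batch Optional per-sample batch labels carried through.
#' @return A `promoter_methylation`: list with `values` (samples x
#'   promoters), `genes`, `promoter_ids`, `batch`.
#' @export
aggregate_promoters <- function(betas, map, batch = NULL) {
  if (nrow(map) == 0) {
    mc_abort("empty promoter map", "methclock_validation_error")
  }
  x <- unclass(betas)
  map <- map[map$cpg_id %in% colnames(x), , drop = FALSE]
  if (nrow(map) == 0) {
    mc_abort("no promoter-map CpGs present in the beta matrix",
             "methclock_validation_error")
  }
  key <- paste(map$gene, map$chrom, map$start, map$end, sep = "|")
  promoters <- unique(key)
  # membership matrix CpGs-present x promoters; mean via masked matrix product
  memb <- matrix(0, nrow = ncol(x), ncol = length(promoters),
                 dimnames = list(colnames(x), promoters))
  memb[cbind(match(map$cpg_id, colnames(x)), match(key, promoters))] <- 1
  present <- 1 - is.na(x)
  x0 <- x; x0[is.na(x0)] <- 0
  sums <- x0 %*% memb
  counts <- present %*% memb
  vals <- sums / counts
  vals[counts == 0] <- NA_real_
  first <- match(promoters, key)
  structure(list(values = vals,
                 genes = map$gene[first],
                 promoter_ids = promoters,
                 batch = batch),
            class = "promoter_methylation")
}

#' Within-batch location normalization of promoter methylation
#'
#' Per promoter, subtracts the batch mean and adds back the grand mean, so
#' batch means agree after normalization while the per-promoter grand mean
#' is preserved (pre-clipping); values are then clipped to \[0, 1\]. Scale
#' is untouched. A single batch is a no-op.
#'
#' @param pm A `promoter_methylation`.
#' @param batch Per-sample batch labels (defaults to `pm$batch`).
#' @return A `promoter_methylation` with normalized values.
#' @export
batch_normalize <- function(pm, batch = pm$batch) {
  if (is.null(batch)) {
    mc_abort("batch labels required", "methclock_validation_error")
  }
  b <- as_covariate(batch)
  if (length(b) != nrow(pm$values)) {
    mc_abort("batch length must match sample count",
             "methclock_validation_error")
  }
  if (min(table(b)) < 2) {
    mc_abort("single-sample batch: cannot estimate batch offset",
             "methclock_validation_error")
  }
  if (nlevels(b) == 1) {
    pm$batch <- batch
    return(pm)
  }
  v <- pm$values
  grand <- colMeans(v, na.rm = TRUE)
  for (l in levels(b)) {
    idx <- which(b == l)
    bm <- colMeans(v[idx, , drop = FALSE], na.rm = TRUE)
    v[idx, ] <- sweep(v[idx, , drop = FALSE], 2, bm - grand)
  }
  pm$values <- pmin(pmax(v, 0), 1)
  pm$batch <- batch
  pm
}

#' Per-promoter two-group differential methylation
#'
#' Welch t-test per promoter with Benjamini-Hochberg adjustment across all
#' testable promoters. Sign convention: t > 0 means higher methylation in
#' the case (second factor level, e.g. `pgd = TRUE`) group. Promoters with
#' zero variance in both groups are reported as NA and excluded from the BH
#' family size.
#'
#' @param pm A `promoter_methylation`.
#' @param group Two-level grouping vector (cases = second level after
#'   alphabetical ordering, so logical `pgd` puts cases at `TRUE`).
#' @return Data.frame of class `diff_meth_table`: `promoter`, `gene`,
#'   `mean_control`, `mean_case`, `t`, `df`, `p`, `q`.
#' @export
promoter_tests <- function(pm, group) {
  g <- as_covariate(group)
  if (nlevels(g) != 2 || min(table(g)) < 2) {
    mc_abort("need two groups with >= 2 samples each",
             "methclock_validation_error")
  }
  ctrl <- pm$values[g == levels(g)[1], , drop = FALSE]
  case <- pm$values[g == levels(g)[2], , drop = FALSE]
  n1 <- colSums(!is.na(ctrl)); n2 <- colSums(!is.na(case))
  m1 <- colMeans(ctrl, na.rm = TRUE); m2 <- colMeans(case, na.rm = TRUE)
  v1 <- apply(ctrl, 2, stats::var, na.rm = TRUE)
  v2 <- apply(case, 2, stats::var, na.rm = TRUE)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m2 - m1) / sqrt(se2)
  dfree <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tstat), dfree)
  undef <- (v1 == 0 & v2 == 0) | n1 < 2 | n2 < 2
  tstat[undef] <- NA_real_; p[undef] <- NA_real_; dfree[undef] <- NA_real_
  q <- rep(NA_real_, length(p))
  q[!is.na(p)] <- stats::p.adjust(p[!is.na(p)], method = "BH")
  out <- data.frame(promoter = pm$promoter_ids, gene = pm$genes,
                    mean_control = m1, mean_case = m2,
                    t = tstat, df = dfree, p = p, q = q,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("diff_meth_table", "data.frame")
  out
}

#' Gene-set Kolmogorov-Smirnov differential-methylation test
#'
#' For each gene set, compares the distribution of per-promoter t statistics
#' inside the set against all out-of-set promoters by a two-sided two-sample
#' KS test (exact p when both sides have <= 10 promoters, asymptotic
#' otherwise), with Benjamini-Hochberg adjustment across tested sets. Each
#' set is labeled by the sign of its median in-set t: `hypo` (lower
#' methylation in cases), `hyper`, or `none`. Sets with fewer than
#' `min_set_size` mapped promoters are skipped with a warning.
#'
#' @param dm A `diff_meth_table` from [promoter_tests].
#' @param sets A [gene_set_collection].
#' @param top_k Number of top-ranked sets to report (default 15).
#' @param q_threshold FDR threshold for the top report (default 0.01).
#' @param min_set_size Minimum mapped promoters per tested set (default 3).
#' @return List of class `gene_set_result` with `results` (data.frame
#'   ranked by p: `set`, `n_in`, `n_out`, `D`, `p`, `q`, `direction`) and
#'   `top` (the ranked sets with `q < q_threshold`, at most `top_k`).
#' @export
gene_set_ks <- function(dm, sets, top_k = 15, q_threshold = 0.01,
                        min_set_size = 3) {
  tv <- dm$t[!is.na(dm$t)]
  genes <- dm$gene[!is.na(dm$t)]
  rows <- list()
  skipped <- character(0)
  for (nm in names(sets)) {
    inset <- genes %in% sets[[nm]]
    t_in <- tv[inset]; t_out <- tv[!inset]
    if (length(t_in) < min_set_size) {
      skipped <- c(skipped, nm)
      next
    }
    exact <- length(t_in) <= 10 && length(t_out) <= 10
    ht <- suppressWarnings(
      stats::ks.test(t_in, t_out, exact = exact))
    med <- stats::median(t_in)
    rows[[nm]] <- data.frame(
      set = nm, n_in = length(t_in), n_out = length(t_out),
      D = unname(ht$statistic), p = ht$p.value,
      direction = if (med < 0) "hypo" else if (med > 0) "hyper" else "none",
      stringsAsFactors = FALSE)
  }
  if (length(skipped)) {
    mc_warn(sprintf("skipped %d set(s) with < %d mapped promoters: %s",
                    length(skipped), min_set_size,
                    paste(utils::head(skipped, 5), collapse = ", ")),
            "methclock_small_set_warning")
  }
  if (!length(rows)) {
    mc_abort("no gene set had enough mapped promoters",
             "methclock_validation_error")
  }
  res <- do.call(rbind, rows)
  res$q <- stats::p.adjust(res$p, method = "BH")
  res <- res[order(res$p), c("set", "n_in", "n_out", "D", "p", "q",
                             "direction")]
  rownames(res) <- NULL
  top <- utils::head(res[res$q < q_threshold, , drop = FALSE], top_k)
  structure(list(results = res, top = top, q_threshold = q_threshold,
                 top_k = top_k), class = "gene_set_result")
}
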