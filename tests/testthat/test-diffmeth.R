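make_pm <- function(values, genes = sprintf("GENE%02d", seq_len(ncol(values))),
                    batch = NULL) {
  structure(list(values = values, genes = genes,
                 promoter_ids = sprintf("P%02d", seq_len(ncol(values))),
                 batch = batch),
            class = "promoter_methylation")
}

test_that("genome-wide mean comparison handles degenerate and shifted data", {
  const <- beta_matrix(matrix(0.5, 6, 4,
                              dimnames = list(paste0("s", 1:6),
                                              paste0("cg", 1:4))))
  g <- rep(c(TRUE, FALSE), each = 3)
  res <- global_mean_compare(const, g)
  expect_equal(unname(res$group_means), c(0.5, 0.5))
  expect_equal(res$p, 1)

  shifted <- unclass(const)
  shifted[g, ] <- 0.6
  res2 <- global_mean_compare(beta_matrix(shifted), g)
  expect_equal(res2$p, 0)  # perfect separation flag

  with_missing <- unclass(const)
  with_missing[1, ] <- NA
  expect_warning(res3 <- global_mean_compare(beta_matrix(with_missing), g),
                 class = "methclock_missing_sample_warning")
  expect_length(res3$sample_means, 5)
})

test_that("promoter aggregation averages CpGs with mapping semantics", {
  vals <- matrix(c(0.2, 0.4, 0.6,
                   0.4, 0.6, 0.8), nrow = 2, byrow = TRUE,
                 dimnames = list(c("s1", "s2"), c("cg1", "cg2", "cg3")))
  map <- promoter_map(data.frame(
    cpg_id = c("cg1", "cg2", "cg2"),  # cg2 in two overlapping promoters
    gene = c("G1", "G1", "G2"),
    chrom = "chr1", start = c(0, 0, 100), end = c(50, 50, 200),
    strand = "+"))
  pm <- aggregate_promoters(beta_matrix(vals), map)
  expect_equal(ncol(pm$values), 2L)
  expect_equal(unname(pm$values[1, ]), c(mean(c(0.2, 0.4)), 0.4))
  expect_equal(unname(pm$values[2, ]), c(mean(c(0.4, 0.6)), 0.6))
  # single-CpG promoter equals that CpG's beta
  map1 <- promoter_map(data.frame(cpg_id = "cg3", gene = "G3",
                                  chrom = "chr1", start = 300, end = 400,
                                  strand = "-"))
  pm1 <- aggregate_promoters(beta_matrix(vals), map1)
  expect_equal(unname(pm1$values[, 1]), c(0.6, 0.8))

  expect_error(aggregate_promoters(beta_matrix(vals), map[0, ]),
               class = "methclock_validation_error")
})

test_that("batch normalization equalizes batch means, preserves contrasts", {
  withr::with_seed(91, {
    base <- matrix(runif(40, 0.3, 0.7), 8, 5)
    batch <- rep(c("B1", "B2"), each = 4)
    shifted <- base
    shifted[batch == "B2", ] <- shifted[batch == "B2", ] + 0.1
    pm <- make_pm(shifted)
    out <- batch_normalize(pm, batch)
    for (j in 1:5) {
      expect_equal(mean(out$values[batch == "B1", j]),
                   mean(out$values[batch == "B2", j]), tolerance = 1e-12)
      expect_equal(mean(out$values[, j]), mean(shifted[, j]),
                   tolerance = 1e-12)
    }
    # groups balanced across batches: within-batch group contrast unchanged
    grp <- rep(c(TRUE, FALSE), 4)
    d_before <- colMeans(shifted[grp & batch == "B1", ]) -
      colMeans(shifted[!grp & batch == "B1", ])
    d_after <- colMeans(out$values[grp & batch == "B1", ]) -
      colMeans(out$values[!grp & batch == "B1", ])
    expect_equal(d_before, d_after, tolerance = 1e-12)

    single <- batch_normalize(make_pm(base), rep("B1", 8))
    expect_equal(single$values, base)

    expect_error(batch_normalize(pm, c(rep("B1", 7), "B2")),
                 class = "methclock_validation_error")
  })
})

test_that("promoter Welch tests match t.test, honor sign and BH rules", {
  withr::with_seed(101, {
    vals <- matrix(runif(120, 0.2, 0.8), 12, 10)
    grp <- rep(c(FALSE, TRUE), each = 6)
    vals[grp, 1] <- vals[grp, 1] + 0.15  # promoter 1 higher in cases
    pm <- make_pm(vals)
    dm <- promoter_tests(pm, grp)
    for (j in c(1, 4, 7)) {
      tt <- t.test(vals[grp, j], vals[!grp, j])
      expect_equal(dm$t[j], unname(tt$statistic), tolerance = 1e-10)
      expect_equal(dm$p[j], tt$p.value, tolerance = 1e-10)
    }
    expect_gt(dm$t[1], 0)  # t > 0 means higher in cases
    expect_true(all(dm$q >= dm$p, na.rm = TRUE))
    expect_equal(dm$q, bh_oracle(dm$p))

    # zero variance in both groups -> NA, excluded from the BH family
    vals0 <- vals
    vals0[, 2] <- 0.5
    dm0 <- promoter_tests(make_pm(vals0), grp)
    expect_true(is.na(dm0$t[2]))
    expect_equal(dm0$q[-2], bh_oracle(dm0$p[-2]))

    one <- promoter_tests(make_pm(vals[, 1, drop = FALSE]), grp)
    expect_equal(one$q, one$p)
  })
})

test_that("null promoter tests rarely pass FDR", {
  hits <- vapply(1:40, function(s) {
    withr::with_seed(300 + s, {
      vals <- matrix(plogis(rnorm(28 * 200, 0, 1)), 28, 200)
      grp <- rep(c(TRUE, FALSE), c(13, 15))
      dm <- promoter_tests(make_pm(vals), grp)
      sum(dm$q < 0.05, na.rm = TRUE)
    })
  }, numeric(1))
  expect_gte(mean(hits == 0), 0.9)
})

test_that("gene-set KS matches small-sample enumeration and tie behavior", {
  dm <- structure(data.frame(
    promoter = paste0("P", 1:4), gene = c("A1", "A2", "B1", "B2"),
    mean_control = 0.5, mean_case = 0.5,
    t = c(-2, -1, 1, 2), df = 10, p = 0.5, q = 0.5),
    class = c("diff_meth_table", "data.frame"))
  sets <- gene_set_collection(list(DOWN = c("A1", "A2")))
  res <- gene_set_ks(dm, sets, min_set_size = 2)
  expect_equal(res$results$D, 1)
  expect_equal(res$results$p, 1 / 3, tolerance = 1e-12)
  expect_equal(res$results$direction, "hypo")

  # in-set values identical to out-of-set values -> D = 0
  dm$t <- c(1, 2, 1, 2)
  res0 <- gene_set_ks(dm, sets, min_set_size = 2)
  expect_equal(res0$results$D, 0)

  # sets below the size floor are skipped with a warning
  expect_warning(
    expect_error(gene_set_ks(dm, sets, min_set_size = 3),
                 class = "methclock_validation_error"),
    class = "methclock_small_set_warning")
})

test_that("KS D equals the double-loop oracle on random samples", {
  withr::with_seed(111, {
    for (i in 1:15) {
      a <- rnorm(sample(3:50, 1))
      b <- rnorm(sample(3:50, 1), mean = runif(1, -1, 1))
      expect_equal(unname(suppressWarnings(ks.test(a, b))$statistic),
                   ks_d_oracle(a, b), tolerance = 1e-12)
    }
  })
})

test_that("the diffmeth pipeline is invariant to sample order", {
  sim <- simulate_cohort(tiny_config(seed = 121))
  pm <- aggregate_promoters(sim$betas, sim$promoters,
                            batch = sim$samples$batch)
  run <- function(perm) {
    p2 <- pm
    p2$values <- pm$values[perm, , drop = FALSE]
    p2$batch <- pm$batch[perm]
    dm <- promoter_tests(batch_normalize(p2), sim$samples$pgd[perm])
    gene_set_ks(dm, sim$gene_sets, min_set_size = 3)$results
  }
  n <- nrow(pm$values)
  r1 <- run(seq_len(n))
  r2 <- run(withr::with_seed(5, sample(n)))
  expect_equal(r1, r2, tolerance = 1e-10)
})
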