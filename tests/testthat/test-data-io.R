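test_that("beta matrix TSV parses, round-trips losslessly, and validates", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tcg1\tcg2", "s1\t0.1\t0.9", "s2\t0.25\t"), path)
  bm <- read_beta_matrix(path)
  expect_equal(dim(bm), c(2L, 2L))
  expect_equal(unname(bm["s1", ]), c(0.1, 0.9))
  expect_true(is.na(bm["s2", "cg2"]))

  vals <- matrix(runif(12), 3, 4,
                 dimnames = list(paste0("s", 1:3), paste0("cg", 1:4)))
  vals[2, 3] <- NA
  bm2 <- beta_matrix(vals)
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_beta_matrix(bm2, p2)
  back <- read_beta_matrix(p2)
  expect_identical(dimnames(back), dimnames(bm2))
  expect_equal(unclass(back), unclass(bm2), tolerance = 1e-12)

  # transposed layout
  p3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("cpg_id\ts1\ts2", "cg1\t0.1\t0.2", "cg2\t0.3\t0.4"), p3)
  bt <- read_beta_matrix(p3, transpose = TRUE)
  expect_equal(rownames(bt), c("s1", "s2"))
  expect_equal(unname(bt["s2", "cg1"]), 0.2)
})

test_that("beta matrix readers reject invalid cells with typed errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tcg1", "s1\t1.2"), path)
  expect_error(read_beta_matrix(path), "\\[0,1\\]",
               class = "methclock_validation_error")

  writeLines(c("sample_id\tcg1", "s1\tabc"), path)
  expect_error(read_beta_matrix(path), "non-numeric",
               class = "methclock_parse_error")

  writeLines(c("sample_id\tcg1", "s1\t0.5", "s1\t0.6"), path)
  expect_error(read_beta_matrix(path), class = "methclock_format_error")
})

test_that("sample table reads, validates the survival triple, round-trips", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "sample_id,donor_age,recipient_age,pgd,batch,entry_time,event_time,event,extra",
    "a,30,55,TRUE,B1,365,900,FALSE,x",
    "b,45,60,FALSE,B2,370,500,TRUE,y",
    "c,50,40,FALSE,B1,360,2000,FALSE,z"), path)
  tab <- read_sample_table(path)
  expect_s3_class(tab, "sample_table")
  expect_equal(nrow(tab), 3L)
  expect_true("extra" %in% names(tab))  # unknown columns preserved

  writeLines(c(
    "sample_id,donor_age,recipient_age,pgd,batch,entry_time,event_time,event",
    "a,30,55,TRUE,B1,400,370,FALSE"), path)
  expect_error(read_sample_table(path), "precedes",
               class = "methclock_validation_error")

  writeLines(c("sample_id,donor_age,pgd", "a,30,TRUE"), path)
  expect_error(read_sample_table(path), class = "methclock_schema_error")

  # synthetic-cohort output round-trips losslessly
  sim <- simulate_cohort(tiny_config(seed = 11))
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_sample_table(sim$samples, p2)
  back <- read_sample_table(p2)
  for (col in names(sim$samples)) {
    expect_equal(back[[col]], sim$samples[[col]], tolerance = 1e-12)
  }
})

test_that("GMT parsing de-duplicates genes and reports malformed lines", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines("HYPOXIA\tdesc\tG1\tG2", path)
  sets <- read_gene_sets(path)
  expect_equal(sets$HYPOXIA, c("G1", "G2"))

  writeLines("HYPOXIA\tdesc\tG1\tG2\tG1", path)
  expect_equal(read_gene_sets(path)$HYPOXIA, c("G1", "G2"))

  writeLines(c("OK\tdesc\tG1", "BROKEN\tdesc"), path)
  expect_error(read_gene_sets(path), "line 2",
               class = "methclock_format_error")

  # a Hallmark-scale collection round-trips with 50 sets
  big <- gene_set_collection(stats::setNames(
    lapply(1:50, function(i) sprintf("G%03d_%d", 1:8, i)),
    sprintf("SET%02d", 1:50)))
  p2 <- withr::local_tempfile(fileext = ".gmt")
  write_gene_sets(big, p2)
  back <- read_gene_sets(p2)
  expect_length(back, 50L)
  expect_identical(unclass(back), unclass(big))
})

test_that("BED-like promoter map parses, validates coordinates, round-trips", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t100\t2100\tGENE1\tcg0001\t+", path)
  pm <- read_promoter_map(path)
  expect_equal(nrow(pm), 1L)
  expect_equal(pm$gene, "GENE1")
  expect_equal(pm$cpg_id, "cg0001")
  expect_equal(pm$start, 100L)

  writeLines("chr1\t2100\t100\tGENE1\tcg0001\t+", path)
  expect_error(read_promoter_map(path), class = "methclock_coordinate_error")

  sim <- simulate_cohort(tiny_config(seed = 3))
  p2 <- withr::local_tempfile(fileext = ".bed")
  write_promoter_map(sim$promoters, p2)
  back <- read_promoter_map(p2)
  expect_equal(as.data.frame(back), as.data.frame(sim$promoters))
})

test_that("clock model JSON serialization is an identity and checks schema", {
  m <- clock_model(c("cg1", "cg2", "cg3"), c(0.5, -0.2, 0.01),
                   intercept = 0.3, adult_age = 20,
                   training_means = c(0.4, 0.5, 0.6),
                   training_meta = list(note = "fixture"))
  path <- withr::local_tempfile(fileext = ".json")
  serialize_clock(m, path)
  back <- load_clock(path)
  expect_equal(back$cpg_ids, m$cpg_ids)
  expect_equal(back$weights, m$weights)
  expect_equal(back$intercept, m$intercept)
  expect_equal(back$adult_age, m$adult_age)
  expect_equal(back$training_means, m$training_means)

  obj <- jsonlite::read_json(path)
  obj$adult_age <- NULL
  jsonlite::write_json(obj, path, auto_unbox = TRUE)
  expect_error(load_clock(path), "adult_age",
               class = "methclock_schema_error")

  expect_error(clock_model("cg1", c(1, 2), 0, 20),
               class = "methclock_schema_error")
})
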