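# Synthetic methylation-cohort generator.
#
# Generates cohorts with the statistical structure the analysis assumes:
# age-driven clock-CpG methylation on the logit scale, additive batch
# offsets, an injury (PGD) age-acceleration effect, pathway-restricted
# promoter hypomethylation, and exponential proportional-hazards survival
# with delayed (left-truncated) entry. Ground truth is returned for
# parameter-recovery tests.

hallmark_like_names <- c(
  "HYPOXIA", "TNFA_SIGNALING_VIA_NFKB", "MTORC1_SIGNALING",
  "IL2_STAT5_SIGNALING", "GLYCOLYSIS", "INFLAMMATORY_RESPONSE",
  "E2F_TARGETS", "APOPTOSIS")

#' Simulation configuration
#'
#' Defaults describe the study conditions the package emulates: a 28-subject
#' case-control cohort (13 severe-PGD cases, 15 controls), a 761-CpG clock,
#' two array-processing batches, a 6.5-year PGD age acceleration, an
#' apparent-age attenuation slope of 0.38 per year of graft age, and
#' CLAD-or-death follow-up with entry at the ~1-year airway brush. The
#' promoter compartment is scaled down from array size: 1000 genes in 50
#' Hallmark-like sets of 20 genes, 3 CpGs per promoter.
#'
#' @param n_subjects Cohort size.
#' @param n_clock_cpgs Clock CpG count (default 761).
#' @param n_genes Number of genes with simulated promoters.
#' @param cpgs_per_promoter CpGs per promoter.
#' @param n_gene_sets Number of gene sets (genes are partitioned evenly).
#' @param affected_set_names Sets whose promoters are hypomethylated in PGD
#'   subjects; must be generated set names.
#' @param pgd_fraction Fraction of subjects with severe PGD; the realized
#'   count is `round(pgd_fraction * n_subjects)`.
#' @param donor_age_range,recipient_age_range Uniform age ranges (years).
#' @param pgd_acceleration PGD shift of true epigenetic age, years
#'   (default 6.5).
#' @param age_slope_attenuation Slope of apparent (clock-scale) age per year
#'   of true age (default 0.38), modeling tissue-specific attenuation.
#' @param age_offset Additive offset of apparent age (years).
#' @param age_noise_sd SD of subject-level true-age noise, years (default 9;
#'   calibrated so apparent age vs graft age attains R-squared near 0.67).
#' @param cpg_noise_sd Logit-scale CpG noise SD.
#' @param batch_offsets Logit-scale additive offset per batch; the length
#'   sets the number of batches.
#' @param hypomethylation_delta Beta-scale hypomethylation of affected-set
#'   promoters in PGD subjects.
#' @param baseline_hazard Exponential baseline hazard, per day.
#' @param log_hazard_per_year Log hazard per year of true epigenetic age.
#' @param censor_time Administrative censoring, days post-transplant.
#' @param adult_age Age-transform anchor used for the clock signal.
#' @param seed Integer seed for subject-level draws.
#' @param coef_seed Optional separate seed for CpG coefficients and the
#'   gene-set partition, so cohorts drawn under different `seed`s share one
#'   CpG architecture (needed when one trained clock serves many cohorts).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 28, n_clock_cpgs = 761, n_genes = 1000,
                       cpgs_per_promoter = 3, n_gene_sets = 50,
                       affected_set_names = c("HYPOXIA",
                                              "TNFA_SIGNALING_VIA_NFKB",
                                              "MTORC1_SIGNALING",
                                              "IL2_STAT5_SIGNALING"),
                       pgd_fraction = 13 / 28,
                       donor_age_range = c(18, 65),
                       recipient_age_range = c(25, 70),
                       pgd_acceleration = 6.5,
                       age_slope_attenuation = 0.38,
                       age_offset = 0,
                       age_noise_sd = 9,
                       cpg_noise_sd = 0.3,
                       batch_offsets = c(0, 0.3),
                       hypomethylation_delta = 0.05,
                       baseline_hazard = 3e-5,
                       log_hazard_per_year = 0.05,
                       censor_time = 2190,
                       adult_age = 20,
                       seed = 1,
                       coef_seed = NULL) {
  cfg <- list(n_subjects = n_subjects, n_clock_cpgs = n_clock_cpgs,
              n_genes = n_genes, cpgs_per_promoter = cpgs_per_promoter,
              n_gene_sets = n_gene_sets,
              affected_set_names = affected_set_names,
              pgd_fraction = pgd_fraction,
              donor_age_range = donor_age_range,
              recipient_age_range = recipient_age_range,
              pgd_acceleration = pgd_acceleration,
              age_slope_attenuation = age_slope_attenuation,
              age_offset = age_offset,
              age_noise_sd = age_noise_sd,
              cpg_noise_sd = cpg_noise_sd,
              batch_offsets = batch_offsets,
              hypomethylation_delta = hypomethylation_delta,
              baseline_hazard = baseline_hazard,
              log_hazard_per_year = log_hazard_per_year,
              censor_time = censor_time,
              adult_age = adult_age,
              seed = seed, coef_seed = coef_seed)
  counts <- c("n_subjects", "n_clock_cpgs", "n_genes", "cpgs_per_promoter",
              "n_gene_sets")
  for (nm in counts) {
    if (!is_scalar_number(cfg[[nm]]) || cfg[[nm]] < 1) {
      mc_abort(sprintf("'%s' must be >= 1", nm), "methclock_config_error")
    }
  }
  if (cfg$pgd_fraction < 0 || cfg$pgd_fraction > 1) {
    mc_abort("pgd_fraction must lie in [0, 1]", "methclock_config_error")
  }
  if (cfg$cpg_noise_sd < 0 || cfg$age_noise_sd < 0) {
    mc_abort("noise SDs must be non-negative", "methclock_config_error")
  }
  if (cfg$hypomethylation_delta < 0) {
    mc_abort("hypomethylation_delta must be non-negative",
             "methclock_config_error")
  }
  if (length(cfg$batch_offsets) < 1) {
    mc_abort("at least one batch offset required", "methclock_config_error")
  }
  set_names <- gene_set_names(cfg$n_gene_sets)
  unknown <- setdiff(cfg$affected_set_names, set_names)
  if (length(unknown)) {
    mc_abort(sprintf("affected set(s) not among generated sets: %s",
                     paste(unknown, collapse = ", ")),
             "methclock_config_error")
  }
  class(cfg) <- c("sim_config", "list")
  cfg
}

gene_set_names <- function(n) {
  base <- hallmark_like_names[seq_len(min(n, length(hallmark_like_names)))]
  if (n > length(base)) {
    base <- c(base, sprintf("PATHWAY_%02d", seq.int(length(base) + 1, n)))
  }
  base
}

# CpG architecture shared by a cohort and its training set: clock-CpG
# logit intercepts/slopes, promoter-CpG intercepts, gene-set partition.
# Drawn from a stream separate from the subject-level stream so that
# fixing coef_seed shares one architecture across many subject seeds.
draw_architecture <- function(config) {
  n_prom_cpg <- config$n_genes * config$cpgs_per_promoter
  withr::with_seed(config$coef_seed %||% (config$seed + 1000003), {
    list(
      clock_a = stats::rnorm(config$n_clock_cpgs, 0, 1),
      clock_b = stats::rnorm(config$n_clock_cpgs, 0, 0.5),
      # promoter-CpG intercepts centered so mean beta is near 0.47
      gene_a = stats::rnorm(n_prom_cpg, -0.12, 1),
      gene_order = sample.int(config$n_genes))
  })
}

build_promoter_map <- function(config) {
  n_genes <- config$n_genes
  k <- config$cpgs_per_promoter
  genes <- sprintf("GENE%04d", seq_len(n_genes))
  chrom <- sprintf("chr%d", ((seq_len(n_genes) - 1) %% 22) + 1)
  tss <- 100000L + 10000L * seq_len(n_genes)
  strand <- rep(c("+", "-"), length.out = n_genes)
  start <- ifelse(strand == "+", tss - 1500L, tss - 500L)
  end <- ifelse(strand == "+", tss + 500L, tss + 1500L)
  promoter_map(data.frame(
    cpg_id = sprintf("cgP%06d", seq_len(n_genes * k)),
    gene = rep(genes, each = k),
    chrom = rep(chrom, each = k),
    start = rep(start, each = k),
    end = rep(end, each = k),
    strand = rep(strand, each = k),
    stringsAsFactors = FALSE))
}

build_gene_sets <- function(config, gene_order) {
  genes <- sprintf("GENE%04d", gene_order)
  per_set <- floor(config$n_genes / config$n_gene_sets)
  if (per_set < 1) {
    mc_abort("fewer genes than gene sets", "methclock_config_error")
  }
  names_ <- gene_set_names(config$n_gene_sets)
  sets <- lapply(seq_len(config$n_gene_sets), function(i) {
    genes[seq.int((i - 1) * per_set + 1, i * per_set)]
  })
  names(sets) <- names_
  gene_set_collection(sets)
}

#' Simulate a case-control methylation cohort
#'
#' Generative model (all on the scales noted):
#' * true epigenetic age `A_i = donor_age_i + delta * pgd_i + eta_i`,
#'   `eta ~ N(0, age_noise_sd^2)` (floored at 0.5 y);
#' * clock CpG betas `logit(beta_ij) = a_j + b_j * F(s * A_i + c) +
#'   batch_offset + eps_ij`, `eps ~ N(0, cpg_noise_sd^2)`, with `F` the
#'   calibrated age transform, `s` the attenuation slope and `c` the
#'   apparent-age offset;
#' * promoter CpG betas `logit(beta_ik) = g_k + batch_offset + eps_ik`;
#'   promoters of genes in the affected sets are shifted by
#'   `-hypomethylation_delta` (beta scale, clipped to \[0, 1\]) in PGD
#'   subjects;
#' * recipient ages drawn independently of donor ages;
#' * survival: entry at the ~1-year brush (uniform 350-385 d), residual
#'   time-to-event exponential with rate
#'   `baseline_hazard * exp(log_hazard_per_year * A_i)`, administratively
#'   censored at `censor_time`.
#'
#' @param config A [sim_config].
#' @return A list with elements `betas` ([beta_matrix]), `samples`
#'   ([sample_table]), `promoters` ([promoter_map]), `gene_sets`
#'   ([gene_set_collection]) and `truth` (a `true_state` list holding the
#'   per-subject true ages, CpG coefficients, affected genes and survival
#'   parameters).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  arch <- draw_architecture(config)
  promoters <- build_promoter_map(config)
  gene_sets <- build_gene_sets(config, arch$gene_order)
  affected_genes <- unique(unlist(gene_sets[config$affected_set_names],
                                  use.names = FALSE))
  n <- config$n_subjects
  n_batches <- length(config$batch_offsets)

  subject <- withr::with_seed(config$seed, {
    donor_age <- stats::runif(n, config$donor_age_range[1],
                              config$donor_age_range[2])
    recipient_age <- stats::runif(n, config$recipient_age_range[1],
                                  config$recipient_age_range[2])
    n_pgd <- round(config$pgd_fraction * n)
    pgd <- rep(FALSE, n)
    pgd[sample.int(n, n_pgd)] <- TRUE
    batch <- sample(rep_len(seq_len(n_batches), n))
    eta <- stats::rnorm(n, 0, config$age_noise_sd)
    A <- pmax(donor_age + config$pgd_acceleration * pgd + eta, 0.5)
    # clock CpG betas
    Fapp <- transform_age(pmax(config$age_slope_attenuation * A +
                                 config$age_offset, 0.5),
                          config$adult_age)
    eps_clock <- matrix(stats::rnorm(n * config$n_clock_cpgs, 0,
                                     config$cpg_noise_sd),
                        n, config$n_clock_cpgs)
    logit_clock <- outer(rep(1, n), arch$clock_a) +
      outer(Fapp, arch$clock_b) +
      config$batch_offsets[batch] + eps_clock
    # promoter CpG betas
    n_prom_cpg <- config$n_genes * config$cpgs_per_promoter
    eps_prom <- matrix(stats::rnorm(n * n_prom_cpg, 0, config$cpg_noise_sd),
                       n, n_prom_cpg)
    logit_prom <- outer(rep(1, n), arch$gene_a) +
      config$batch_offsets[batch] + eps_prom
    beta_prom <- stats::plogis(logit_prom)
    affected_cols <- which(rep(sprintf("GENE%04d", seq_len(config$n_genes)),
                               each = config$cpgs_per_promoter) %in%
                             affected_genes)
    if (length(affected_cols) && any(pgd)) {
      beta_prom[pgd, affected_cols] <-
        pmin(pmax(beta_prom[pgd, affected_cols] -
                    config$hypomethylation_delta, 0), 1)
    }
    # covariates
    donor_sex <- sample(c("M", "F"), n, replace = TRUE, prob = c(0.7, 0.3))
    recipient_sex <- sample(c("M", "F"), n, replace = TRUE)
    donor_bmi <- stats::rnorm(n, 25, 3.7)
    recipient_bmi <- stats::rnorm(n, 26, 4.5)
    donor_white <- stats::runif(n) < 0.5
    recipient_white <- stats::runif(n) < 0.68
    cmv_group <- sample(c("D-R-", "D-R+", "D+R-", "D+R+"), n, replace = TRUE,
                        prob = c(0.14, 0.25, 0.28, 0.33))
    indication <- sample(c("A", "B", "C", "D"), n, replace = TRUE,
                         prob = c(0.08, 0.02, 0.15, 0.75))
    # survival with delayed entry at the brush
    entry <- stats::runif(n, 350, 385)
    rate <- config$baseline_hazard * exp(config$log_hazard_per_year * A)
    t_event <- entry + stats::rexp(n, rate)
    event <- t_event <= config$censor_time
    event_time <- pmin(t_event, config$censor_time)
    list(donor_age = donor_age, recipient_age = recipient_age, pgd = pgd,
         batch = batch, A = A, apparent_age = pmax(
           config$age_slope_attenuation * A + config$age_offset, 0.5),
         logit_clock = logit_clock, beta_prom = beta_prom,
         donor_sex = donor_sex, recipient_sex = recipient_sex,
         donor_bmi = donor_bmi, recipient_bmi = recipient_bmi,
         donor_white = donor_white, recipient_white = recipient_white,
         cmv_group = cmv_group, indication = indication,
         entry = entry, event = event, event_time = event_time)
  })

  clock_ids <- sprintf("cgC%06d", seq_len(config$n_clock_cpgs))
  sample_ids <- sprintf("S%03d", seq_len(n))
  betas <- cbind(stats::plogis(subject$logit_clock), subject$beta_prom)
  dimnames(betas) <- list(sample_ids, c(clock_ids, promoters$cpg_id[
    seq_len(config$n_genes * config$cpgs_per_promoter)]))
  betas <- beta_matrix(betas)

  samples <- sample_table(data.frame(
    sample_id = sample_ids,
    donor_age = subject$donor_age,
    recipient_age = subject$recipient_age,
    pgd = subject$pgd,
    batch = sprintf("B%d", subject$batch),
    donor_sex = subject$donor_sex,
    recipient_sex = subject$recipient_sex,
    donor_bmi = subject$donor_bmi,
    recipient_bmi = subject$recipient_bmi,
    donor_white = subject$donor_white,
    recipient_white = subject$recipient_white,
    cmv_group = subject$cmv_group,
    indication = subject$indication,
    entry_time = subject$entry,
    event_time = subject$event_time,
    event = subject$event,
    stringsAsFactors = FALSE))

  truth <- structure(list(
    age = stats::setNames(subject$A, sample_ids),
    apparent_age = stats::setNames(subject$apparent_age, sample_ids),
    clock_intercepts = stats::setNames(arch$clock_a, clock_ids),
    clock_slopes = stats::setNames(arch$clock_b, clock_ids),
    promoter_intercepts = arch$gene_a,
    affected_genes = affected_genes,
    batch_offsets = config$batch_offsets,
    survival = list(baseline_hazard = config$baseline_hazard,
                    log_hazard_per_year = config$log_hazard_per_year),
    config = config), class = "true_state")

  list(betas = betas, samples = samples, promoters = promoters,
       gene_sets = gene_sets, truth = truth)
}

#' Simulate a clock training set
#'
#' Betas are generated from the same clock-CpG architecture as
#' [simulate_cohort] (shared via `coef_seed`) but with no PGD, batch or
#' attenuation effects: `logit(beta) = a_j + b_j * F(age) + eps`. Ages are
#' uniform on `age_range`, mimicking a broad multi-study training panel.
#' Penalized fitting must handle `n_train` below the CpG count.
#'
#' @param config A [sim_config].
#' @param n_train Number of training samples.
#' @param age_range Training age range in years (default 1-90).
#' @param seed Seed for the training draws (defaults to `config$seed`).
#' @return List with `betas` ([beta_matrix], clock CpGs only) and `ages`.
#' @export
simulate_training_cohort <- function(config, n_train,
                                     age_range = c(1, 90),
                                     seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (!is_scalar_number(n_train) || n_train < 1) {
    mc_abort("n_train must be >= 1", "methclock_config_error")
  }
  arch <- draw_architecture(config)
  out <- withr::with_seed(seed, {
    ages <- stats::runif(n_train, age_range[1], age_range[2])
    Ft <- transform_age(ages, config$adult_age)
    eps <- matrix(stats::rnorm(n_train * config$n_clock_cpgs, 0,
                               config$cpg_noise_sd),
                  n_train, config$n_clock_cpgs)
    logit <- outer(rep(1, n_train), arch$clock_a) +
      outer(Ft, arch$clock_b) + eps
    list(ages = ages, betas = stats::plogis(logit))
  })
  dimnames(out$betas) <- list(sprintf("T%04d", seq_len(n_train)),
                              sprintf("cgC%06d", seq_len(config$n_clock_cpgs)))
  list(betas = beta_matrix(out$betas), ages = out$ages)
}
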