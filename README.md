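# methclock

Epigenetic-age analysis for DNA methylation cohorts, motivated by studies
of lung-allograft aging: does a transplanted airway keep the biologic age
of its donor, and does early injury (severe primary graft dysfunction,
PGD) accelerate it?

The package is aimed at transplant epidemiologists and epigenomics
analysts who start from a CpG beta-value matrix and a clinical sample
sheet. It provides, as one tested pipeline:

* **An epigenetic clock.** Age is modeled on the calibrated transform
  `F(a) = log(a+1) − log(a*+1)` for `a ≤ a*`, else `(a − a*)/(a*+1)`
  (anchor `a*` = 20 y), and predicted as
  `F⁻¹(b₀ + Σⱼ wⱼ βⱼ)` from a sparse weight vector fit by elastic net
  (seeded cross-validation, 1-SE rule; handles p ≫ n). Published weights
  can be loaded from JSON instead of training.
* **Cohort associations.** Pearson correlation, batch-adjusted OLS with
  Wald CIs, exact Mann–Whitney / paired signed-rank tests, a sequential
  nested-model ladder for the PGD effect compared by ANOVA, a
  characteristics table with Shapiro–Wilk-routed tests, and
  methylation-to-graft-age ratio summaries.
* **Survival.** Left-truncated Cox models of CLAD-or-death (entry at the
  airway brush, Efron ties), methylation-age tertiles, Kaplan–Meier
  curves with delayed entry, and a simulation-based power curve over a
  hazard-ratio grid.
* **Differential methylation.** CpG→promoter aggregation, within-batch
  location normalization, per-promoter Welch t tests with
  Benjamini–Hochberg adjustment, and gene-set Kolmogorov–Smirnov tests of
  the t-statistic distribution (in-set vs out-of-set) with hypo/hyper
  direction calls.
* **A synthetic cohort generator** (`simulate_cohort`) producing
  beta matrices, sample sheets, promoter maps, gene sets and ground truth
  with the structure above — age-driven CpG methylation, two-batch
  effects, a 6.5-year PGD age acceleration, pathway-restricted promoter
  hypomethylation, proportional-hazards outcomes — so every stage is
  verifiable by parameter recovery without access to patient data.

See `vignettes/methylation-aging-pipeline.Rmd` for the model details and
design decisions.

## Worked example

```r
library(methclock)

cfg   <- sim_config(seed = 42)                    # 28 subjects, 13 PGD / 15 control
sim   <- simulate_cohort(cfg)
train <- simulate_training_cohort(cfg, n_train = 400, seed = 43)
clock <- train_clock(train$betas, train$ages, seed = 44)
clock
#> <clock_model> 185 CpGs, intercept 0.3329, adult_age 20

meth_age <- predict_age(clock, sim$betas)
round(head(meth_age), 1)
#> S001 S002 S003 S004 S005 S006
#> 22.6 26.1 16.3 21.3  8.0 19.5
```

Airway methylation age tracks the graft's (donor's) chronologic age:

```r
correlate(unname(meth_age), sim$samples$donor_age)[c("r_squared", "p")]
#> $r_squared
#> [1] 0.686
#> $p
#> [1] 5.41e-08
```

i.e. graft age explains ~69% of methylation-age variance here. The
sequential model ladder (every model batch-adjusted) shows the PGD effect
and how much of it donor age absorbs:

```r
sequential_models(sim$samples, unname(meth_age))$table
#>    model rss pgd_estimate pgd_ci_lo pgd_ci_hi   pgd_p  anova_p
#> 1 model0 943         4.76   -0.0508      9.56 0.05229       NA
#> 2 model1 243         3.58    1.0679      6.09 0.00713 1.57e-08
#> 3 model2 221         3.42    0.3770      6.46 0.02969 9.26e-01
#> 4 model3 152         1.71   -3.0359      6.45 0.44531 6.71e-01
```

Rows are nested models (0: PGD + batch; 1: + donor age; 2: + donor
covariates; 3: + recipient covariates); `rss` must be non-increasing, and
`anova_p` flags which additions significantly improve fit (here donor
age). Survival, left-truncated at the brush:

```r
fit_cox(sim$samples, unname(meth_age))$coefficients
#>        term  coef    hr ci_lo ci_hi        p
#> 1 predictor  0.20 1.221 1.095 1.363 0.000346
#> 2   batchB2 -1.12 0.326 0.118 0.902 0.030877
```

a hazard ratio of 1.22 per methylation-age year in this draw. Gene-set
differential methylation recovers the planted hypomethylated pathways,
with direction:

```r
pm <- aggregate_promoters(sim$betas, sim$promoters, batch = sim$samples$batch)
dm <- promoter_tests(batch_normalize(pm), sim$samples$pgd)
head(gene_set_ks(dm, sim$gene_sets)$results, 4)
#>                       set n_in n_out     D        p        q direction
#> 1     IL2_STAT5_SIGNALING   20   980 0.939 2.00e-15 9.99e-14      hypo
#> 2                 HYPOXIA   20   980 0.906 2.11e-14 5.27e-13      hypo
#> 3        MTORC1_SIGNALING   20   980 0.869 2.71e-13 4.52e-12      hypo
#> 4 TNFA_SIGNALING_VIA_NFKB   20   980 0.853 8.17e-13 1.02e-11      hypo
```

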