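---
title: "Methods: epigenetic-age analysis of methylation cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: epigenetic-age analysis of methylation cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`methclock` implements an end-to-end epigenetic-age analysis for DNA
methylation cohorts of the kind collected in lung-transplant studies: an
epigenetic clock (training and prediction), cohort-level association
statistics relating methylation age to donor ("graft") age and to severe
primary graft dysfunction (PGD), left-truncated survival analysis of
CLAD-or-death with a simulation-based power procedure, and promoter-level
differential methylation with gene-set Kolmogorov–Smirnov tests. Because
cohorts of this kind are small and not freely redistributable, the package
ships a synthetic cohort generator that reproduces the statistical structure
every downstream stage assumes, together with its ground truth, so the whole
pipeline is verifiable by parameter recovery.

The pipeline starts from a beta-value matrix; IDAT-level array
preprocessing, probe QC and normalization are out of scope.

# The clock model

Methylation age is a sparse linear predictor on a calibrated transform of
age. The transform is the standard piecewise log/linear calibration with an
*adult age* anchor $a^\*$ (default 20 y):

$$F(a) = \begin{cases}\log(a+1) - \log(a^\*+1), & a \le a^\*\\
 (a-a^\*)/(a^\*+1), & a > a^\*\end{cases}$$

$F$ is continuous, strictly increasing, has $F(a^\*)=0$, and an exact
inverse; predictions are computed as
$\hat a = F^{-1}(b_0 + \sum_j w_j \beta_j)$. Training fits
$F(\text{age}) \sim \beta$ by elastic net (mixing parameter $\alpha = 0.5$;
penalty chosen by seeded 10-fold cross-validation with the 1-SE rule, so
ties break toward the stronger penalty). These defaults are standard
practice for clock fitting; both are arguments. The penalized fit handles
more CpGs than samples. Only nonzero-weight CpGs enter the stored model,
along with their training-mean betas: probes missing at prediction time are
imputed with training means — never zero, which is an extreme beta — and
the imputed fraction is reported in a warning. Prediction is strictly
per-sample, so predicting batch subsets separately and pooling is identical
to pooled prediction (asserted as a test); batch handling belongs to the
downstream models, where batch always enters as a fixed-effect covariate.

The package trains its own clock on synthetic data rather than shipping
published clock weights; externally supplied weights can be loaded from the
documented JSON schema (`load_clock`).

# What the generator emulates

`simulate_cohort` draws, for `n_subjects` (default 28, split 13 PGD / 15
control as in the motivating design):

* **True epigenetic age** $A_i = \text{donor age}_i + \delta\,\text{pgd}_i
  + \eta_i$, with $\delta = 6.5$ y and $\eta \sim N(0, \tau^2)$. Donor ages
  are uniform on 18–65 y; recipient ages are drawn independently, matching
  the expectation that graft methylation age tracks the donor, not the
  recipient.
* **Clock CpG betas** on the logit scale:
  $\operatorname{logit}\beta_{ij} = a_j + b_j F(sA_i + c) +
  \text{batch}_{b(i)} + \varepsilon_{ij}$, with $a_j \sim N(0,1)$,
  $b_j \sim N(0, 0.5^2)$, $\varepsilon \sim N(0, \sigma^2)$. The
  attenuation slope $s = 0.38$ and offset $c = 0$ make apparent clock ages
  roughly a third of graft age, emulating the "younger" airway ages seen
  when a predominantly blood-trained clock is applied to airway epithelium.
  A consequence worth stating plainly: on the *apparent* (methylation-age)
  scale the PGD contrast is $s\delta \approx 2.5$ y, while recovery of the
  full $\delta$ is available on the true-age scale, which is what the
  parameter-recovery tests check.
* **Promoter compartment**: 1000 genes × 3 CpGs per promoter, partitioned
  into 50 Hallmark-like sets of 20 genes (a ~13× scale-down of a 40k-CpG
  promoter annotation that keeps realistic set sizes). Promoters of genes
  in the affected sets (default: hypoxia, TNFα, mTORC1 and IL2–STAT5
  signaling) are shifted by $-\Delta$ (beta scale, default 0.05, clipped to
  $[0,1]$) in PGD subjects only.
* **Survival**: entry at the ~1-year brush (uniform 350–385 d
  post-transplant); residual time to CLAD-or-death is exponential with rate
  $\lambda_0 e^{\beta_{\text{surv}} A_i}$ ($\lambda_0 = 3\times 10^{-5}$/d,
  $\beta_{\text{surv}} = 0.05$/y), censored administratively at 6 y. The
  exponential baseline is the simplest proportional-hazards-compatible
  choice; Cox recovery is insensitive to the baseline shape.

Logit-normal betas keep values in $(0,1)$ with realistic heteroskedasticity.
Two parameters have no published value and were fixed once on design
grounds: the subject-level noise $\tau = 9$ y, chosen analytically so the
apparent-age vs graft-age $R^2$ is near 0.67 under the default design
(variance decomposition $184/(184+10.5+81) \approx 0.67$ with donor-age
variance 184, PGD-split variance 10.5), and the CpG noise
$\sigma = 0.3$ logits (≈0.06–0.08 beta-scale SD at mid-range betas) with a
batch offset of 0.3 logits for the second of two batches, both typical
array magnitudes.

What the generator does **not** emulate: probe-level Infinium chemistry and
probe-type effects, detection failures, cell-type composition shifts, SNP
artifacts, and correlated noise across CpGs. Passing recovery tests
therefore demonstrates the correctness of the statistical machinery under
the assumed model, not robustness to those real-data features.

Reproducibility: all subject-level draws come from `seed`. The CpG
architecture (clock intercepts/slopes, promoter intercepts, set partition)
comes from a separate stream, `coef_seed`, so one trained clock can be
applied across many cohort replicates sharing an architecture; by default
`coef_seed` is derived from `seed`.

# Association statistics

`fit_linear` is ordinary least squares with Wald $t$ confidence intervals;
categorical covariates are dummy-coded against the alphabetically first
level. `sequential_models` fits the four nested models of methylation age —
PGD + batch; adding donor age; adding donor sex/BMI/CMV/White ethnicity;
adding recipient age/sex/BMI/ethnicity and transplant indication — and
compares successive fits by ANOVA F-tests. Batch is a covariate in *every*
model, including the "unadjusted" one. Missing covariates are an error:
a 28-subject design does not support silent case dropping or imputation.

`cohort_table` routes continuous variables by per-group Shapiro–Wilk at
$\alpha = 0.05$ (either group non-normal → Mann–Whitney with median [IQR];
otherwise Student's t with mean (SD)); categoricals use chi-squared with
Yates correction for 2×2 tables only, and single-level variables are
reported untested. No multiplicity adjustment is applied across rows, which
matches how such tables are conventionally presented. Quantiles throughout
are type 7 (linear interpolation), the most common default.

`two_group_test` uses the exact Mann–Whitney distribution for combined
n ≤ 20 without ties and the tie-corrected normal approximation otherwise;
the paired signed-rank mode requires complete 1:1 pairs and returns p = 1
when all differences vanish (no evidence, rather than an error).

# Survival analysis

`fit_cox` maximizes the Cox partial likelihood with delayed entry — risk
sets restricted to subjects with `entry_time < t <= event_time`, so the
time origin stays at transplant while observation begins at the brush —
with Efron tie handling (better than Breslow at no cost). Tertiles use
type-7 cutpoints at 33⅓/66⅔% with ties going to the lower tertile; the
tertile model is run both as an ordinal per-tertile coefficient and as a
top-tertile indicator, since both contrasts are of interest. Monotone
likelihood (perfect separation) is flagged with the coefficient direction
rather than silently reported.

The power procedure reconstructs the design-stage question "what effect
could this follow-up structure detect?": for each hazard ratio on a grid,
predictors are redrawn from a normal with the observed moments, event times
are simulated by inverse-transform sampling from the Nelson–Aalen baseline
cumulative hazard of the observed data conditional on each subject's entry
time, censoring reuses each subject's observed follow-up end, the
left-truncated Cox model is refit, and a logistic curve of the rejection
indicator on the hazard ratio yields power at the query HR. Only predictor
values and event times are redrawn; entry and censoring structure are held
at their observed values. Simulated events land on the observed event-time
grid (a step-function inversion); at the default design this procedure is
correctly sized (rejection at HR = 1 close to $\alpha$, asserted as a
test).

# Differential methylation

Promoter methylation is the unweighted mean of a promoter's CpG betas per
sample; CpGs without a promoter are dropped and a CpG in overlapping
promoters contributes to each. The synthetic promoter window is
[TSS−1500, TSS+500) on the coding strand, 0-based half-open — a common
promoter definition. Batch normalization is per-promoter location
adjustment (subtract batch mean, add back grand mean, clip to $[0,1]$):
the minimal intervention consistent with "normalized within batches", it
preserves within-batch group contrasts exactly and leaves scale untouched;
z-scoring would also equalize variances but destroys the beta scale, so it
was not adopted. Per-promoter tests are Welch t (robust to unequal
variances at no practical cost), with t > 0 meaning higher methylation in
cases, and Benjamini–Hochberg adjustment across the testable promoters;
promoters with zero variance in both groups are undefined and excluded from
the family size.

Gene-set testing compares the in-set t-statistic distribution against
**out-of-set** promoters (not all promoters, which would compare a set
partly against itself) by a two-sided two-sample KS test — exact when both
sides have ≤ 10 promoters, asymptotic otherwise — with BH adjustment across
tested sets, a ≥ 3-promoter floor per tested set, and a hypo/hyper label
from the median in-set t. Genes in multiple sets are tested in each.

# Numerical and testing choices

Problem sizes were chosen so each verification stage is a desk-scale
computation: clock recovery uses 400 training samples over ages 1–90 and a
28-subject cohort; PGD recovery uses 200 replicate cohorts; power
calibration uses 1000 simulations per grid point; gene-set detection and
null behavior use 100 seeded replicates each. Independent oracles back the
statistical machinery in the test suite: full enumeration for the exact
Mann–Whitney p, the step-up definition for BH, a double-loop empirical-CDF
scan for the KS statistic, and a brute-force partial-likelihood grid
(|β| ≤ 3, step 10⁻³) for the Cox estimate. Degenerate inputs have
documented contracts rather than accidents: all-tied group tests give
p = 1, constant Cox predictors give HR 1 / p 1, fewer than three distinct
tertile values collapse to one group with a warning, and a zero-variance
genome-wide comparison returns p = 1 (equal means) or 0 (separation).

# Known limitations

* The generator's independence assumptions (CpGs independent given age,
  batch and set membership) make detection easier than on arrays with
  correlated probes; detection rates here are upper bounds.
* The attenuation mechanism composes the clock signal with $sA + c$; it
  reproduces the apparent-age slope and offset but, as noted, scales the
  apparent PGD contrast by $s$ as well.
* Asymptotic KS p-values with small in-set counts (here 20) are
  conservative; exact p-values are used only for tiny sets.
* The power procedure treats the predictor as normal with observed moments
  and keeps censoring fixed; it does not model uncertainty in the baseline
  hazard estimate.
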