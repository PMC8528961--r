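Package: methclock
Title: Epigenetic Clock Age Analysis for Transplant Methylation Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for epigenetic-age analysis of DNA methylation cohorts,
    motivated by studies of lung-allograft aging. Implements a calibrated
    piecewise log/linear age transform and elastic-net epigenetic clock
    training and prediction from CpG beta-value matrices; a synthetic
    cohort generator with age-driven CpG methylation, batch effects, an
    injury-driven age-acceleration effect, pathway-restricted promoter
    hypomethylation and proportional-hazards survival outcomes;
    cohort-level association statistics (correlation, group tests,
    sequential nested regression models, characteristics tables);
    left-truncated Cox survival modeling with simulation-based power; and
    batch-normalized promoter differential methylation with gene-set
    Kolmogorov-Smirnov tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    survival,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
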