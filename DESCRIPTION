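Package: mrphewas
Title: Phenome-Wide Two-Sample Mendelian Randomisation from GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-sample Mendelian randomisation (MR) pipeline for
    phenome-wide scans of many exposures against one or more case-control
    outcomes using only GWAS summary statistics.  Provides harmonisation of
    exposure and outcome associations, instrument quality control (genome-wide
    significance, minor allele frequency, greedy LD pruning, variance-explained
    and F-statistic gates), seven causal estimators (Wald ratio, fixed- and
    multiplicative random-effects inverse-variance weighting, MR-Egger
    regression, weighted median, weighted mode, robust adjusted profile
    score), heterogeneity and sensitivity diagnostics (Cochran Q and I-squared,
    radial Rucker Q, leave-one-out, named-SNP exclusion, forest tables),
    Bonferroni/suggestive classification with a-priori power for binary
    outcomes, and a summary-statistics simulator with known ground truth for
    calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
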