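Package: twinvar
Title: Differential Methylation and Methylation Variability Analysis for
    Disease-Discordant Twin Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for epigenome-wide association analysis of
    disease-discordant monozygotic twin pairs assayed on methylation
    BeadChip arrays. Implements probe-level quality-control filtering
    (detection p-value, sex chromosomes, SNP proximity, cross-reactive
    probes, bead counts), beta/M-value transforms and a probe-type
    quantile normalisation step, differential methylation testing with a
    sibling-pair random effect, differential variability detection by the
    two-stage Bartlett/t-test (iEVORA-style) procedure, reference-based
    cell-composition deconvolution, CpG feature enrichment by repeated
    random sampling, probe-number-bias-adjusted gene-set testing via the
    Wallenius noncentral hypergeometric distribution, overlap tests
    against external probe and gene signatures, and assessment of a
    variability signature in an independent cohort. Ships a synthetic
    twin-cohort generator with known injected mean and variance effects
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    lmerTest,
    pracma,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), withr, cluster, fgsea
Config/testthat/edition: 3
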