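Package: mrnc
Title: Negative Control Outcomes for Detecting Population Stratification
    in Mendelian Randomization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-sample summary-data Mendelian randomization (MR) with a
    negative-control-outcome diagnostic for residual population
    stratification. Reads and harmonizes GWAS summary statistics, computes
    inverse-variance weighted, MR-Egger, weighted-median and weighted-mode
    causal estimates, and runs the two-step negative-control procedure:
    MR of the exposure, and of the outcome, on a predetermined negative
    control phenotype such as tanning ability or hair colour. A
    Balding-Nichols structured-population simulator generates stratified
    cohorts and per-SNP association scans so the whole pipeline can be
    exercised and calibrated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
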