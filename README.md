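# mrnc — negative control outcomes for two-sample Mendelian randomization

`mrnc` is an R package for analysts running two-sample summary-data
Mendelian randomization (MR) who need to know whether their GWAS inputs
are contaminated by residual population stratification. It implements the
negative-control-outcome diagnostic: alongside the MR of an exposure X on
an outcome Y, run two extra MR analyses — exposure → negative control and
outcome → negative control — where the negative control is a phenotype
fixed at birth (tanning ability, natural hair colour) that cannot be
causally downstream of X or Y but shares their ancestry-patterned
confounding. Any "effect" found there is spurious by construction, and if
it persists in outlier-robust estimators it points at confounding acting
across *all* instruments — the stratification signature — rather than a
few pleiotropic SNPs.

The package provides:

* **Summary-statistics handling** — `read_summary_stats()` (delimited
  text with a column map), `select_instruments()` (genome-wide
  significance, p < 5×10⁻⁸, at least 5 SNPs), `harmonize()` (allele
  swaps, strand complements, frequency-resolved palindromes).
* **Estimators** — `mr_ivw()` (fixed or multiplicative-random-effects),
  `mr_egger()`, `mr_weighted_median()`, `mr_weighted_mode()`, all built
  on per-SNP Wald ratios Γ̂ⱼ/γ̂ⱼ with inverse-variance weights; median
  and mode SEs by seeded parametric bootstrap.
* **The diagnostic pipeline** — `run_mr_suite()`,
  `run_negative_control_analysis()`, `flag_stratification()`,
  `render_report()` (results / forest / flags TSVs).
* **A stratified-GWAS simulator** — `sim_config()`, `simulate_cohort()`,
  `run_gwas()`, `make_scenario()`: Balding–Nichols drift across
  subpopulations (Beta(p(1−F)/F, (1−p)(1−F)/F) frequencies), subpopulation
  phenotype shifts, per-SNP OLS scans with none / principal-component /
  true-label adjustment, and presets (`null`, `causal`, `stratified`,
  `stratified_adjusted`, `pleiotropy`) realizing the confounding and
  pleiotropy mechanisms end-to-end with no external data.

A thin command-line wrapper lives at `inst/scripts/mrnc`
(`mrnc run ...`, `mrnc simulate ...`).

## Worked example

Simulate a stratified two-sample study (two cohorts of 10,000, 300 SNPs,
three drifted subpopulations whose mean shifts load on exposure, outcome
and negative control), then run the diagnostic:

```r
library(mrnc)
sc <- make_scenario("stratified", seed = 7)
cfg <- mr_config(seed = 7)
report <- run_negative_control_analysis(sc$exposure, sc$outcome, sc$nc, cfg)
print(report)
#> <nc_report> 2 analysis/analyses, alpha = 0.05
#>   [exposure_on_nc] exposure -> negative control : signal_shared_pattern
#>   [outcome_on_nc] outcome -> negative control : signal_shared_pattern
print(report$triples[[1]]$result)
#> <mr_result_set> exposure -> negative control (J = 157)
#> IVW: beta = 1.033 (SE 0.03415), p = 5.27e-201, 95% CI [0.966, 1.1], J = 157
#> MR-Egger: beta = 0.8787 (SE 0.09164), p = 2.2e-17, 95% CI [0.6977, 1.06], J = 157
#>   intercept = 0.04438 (SE 0.0245), p = 0.072
#> Weighted median: beta = 1.148 (SE 0.02131), p = 0, 95% CI [1.106, 1.189], J = 157
#> Weighted mode: beta = 1.238 (SE 0.04132), p = 2.36e-197, 95% CI [1.157, 1.319], J = 157
```

The exposure appears to "affect" a phenotype fixed at birth — impossible
causally — and the signal survives the weighted median and mode with the
same sign as IVW, so it is not attributable to a few outlying SNPs:
`signal_shared_pattern`, the stratification signature. Re-running the
same analysis on the `stratified_adjusted` preset (scans adjusted for the
true subpopulation labels) returns `no_signal`; the `pleiotropy` preset
instead yields a significant IVW contradicted by the robust estimators
(`signal_outlier_pattern`). `render_report(report, "out/")` writes the
tables.

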