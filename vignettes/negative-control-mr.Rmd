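---
title: "Detecting population stratification with negative control outcomes in two-sample MR"
author: "mrnc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting population stratification with negative control outcomes in two-sample MR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrnc)
```

## The problem

Two-sample summary-data Mendelian randomization (MR) estimates the causal
effect of an exposure $X$ on an outcome $Y$ from per-SNP association
summaries: the SNP–exposure estimates $\hat\gamma_j$ (with standard errors
$\sigma_{\gamma j}$) from one study population and the SNP–outcome
estimates $\hat\Gamma_j$ ($\sigma_{\Gamma j}$) from another. Valid
inference requires the instruments to be unconfounded with the outcome.
Population stratification breaks this: when subpopulations differ in both
allele frequencies (through drift) and phenotype means (through geography,
culture, socioeconomic history), every SNP whose frequency tracks the
structure acquires a spurious association with every structured phenotype.
Principal-component or mixed-model adjustment in the contributing GWAS
often removes much of this, but not reliably all of it.

The diagnostic implemented here uses a *negative control outcome*: a
phenotype that is largely fixed at birth (tanning ability, natural hair
colour, eye colour), so it cannot plausibly be downstream of adult
exposures, yet is strongly patterned by ancestry and therefore subject to
the same stratification. Two extra MR analyses are run for any
exposure–outcome pair of interest:

1. MR of the **exposure** on the negative control;
2. MR of the **outcome** on the negative control (the outcome's own
   genome-wide-significant SNPs become the instruments).

A non-null "effect" in either analysis cannot be causal and signals
residual confounding of the instruments — most plausibly population
stratification when it appears across *all* instruments rather than in a
few outliers. The choice of negative control is scientific, not
mechanical: it must be predetermined relative to the phenotypes of
interest and plausibly exposed to the same confounding; the package
validates nothing about that choice, and a flag is a prompt for further
investigation, not a verdict.

## Estimators

All four standard summary-data estimators are provided, built from the
per-SNP Wald ratios $\hat\beta_j = \hat\Gamma_j/\hat\gamma_j$ with
first-order standard errors $\sigma_{\Gamma j}/|\hat\gamma_j|$ (the
second-order term involving $\sigma_{\gamma j}$ is deliberately omitted —
the usual convention when instruments clear a genome-wide threshold).

* **IVW** — zero-intercept weighted regression of $\hat\Gamma$ on
  $\hat\gamma$ with weights $1/\sigma_{\Gamma j}^2$. The default model is
  multiplicative random effects: the fixed-effect SE is inflated by
  $\max(1, \sqrt{Q/(J-1)})$ with $Q$ Cochran's statistic. The truncation
  at 1 means the test is never anti-conservative relative to the
  fixed-effect analysis, and slightly conservative under exact
  homogeneity.
* **MR-Egger** — the same regression with a free intercept, after
  orienting every $\hat\gamma_j$ positive; the intercept estimates average
  directional pleiotropy under the InSIDE assumption. SEs carry the
  analogous $\max(1, \sqrt{Q'/(J-2)})$ inflation and inference uses
  $t_{J-2}$.
* **Weighted median** — the inverse-variance-weighted median of the Wald
  ratios, by linear interpolation of the sorted ratios at cumulative
  weight $1/2$ (breakpoints $p_j = S_j - w_j/2$, clamped to the extreme
  ratios). Consistent while valid instruments hold $\ge 50\%$ of the
  weight.
* **Weighted mode** — the argmax of a weighted Gaussian kernel density of
  the ratios, bandwidth $\phi \cdot 0.9\,\min(\mathrm{sd},
  \mathrm{MAD}/0.6745)\,J^{-1/5}$ (modified Silverman rule, $\phi = 1$ by
  default), evaluated on a 512-point grid spanning the ratio range, ties
  broken to the smallest grid point. If all ratios coincide the common
  ratio is returned.

Median and mode standard errors come from a parametric bootstrap (default
1000 replicates) that resamples both $\hat\gamma_j^*$ and
$\hat\Gamma_j^*$ from their normal sampling distributions; the seed is a
mandatory argument and the caller's RNG state is never touched, so results
are exactly reproducible. p-values use the normal reference (t for
Egger). Heterogeneity statistics are used internally for the SE inflation
but not reported as diagnostics.

## Instrument selection and harmonization

Instruments are all exposure SNPs with $p < 5\times10^{-8}$ (the
genome-wide convention; configurable), de-duplicated by smallest p-value;
an exposure with fewer than 5 surviving SNPs is refused, mirroring common
exclusion practice. Harmonization aligns each instrument with its outcome
record by rsID: direct matches kept, swapped alleles negated, strand
complements resolved. Palindromic SNPs (A/T, G/C) cannot be resolved from
labels; by default they are kept only when both allele frequencies are
known, both sit outside $0.5 \pm 0.08$, and the frequencies agree with the
label-based orientation — otherwise they are dropped with a recorded
reason. The alternative policy drops all palindromes. The frequency
window 0.08 follows widespread two-sample MR practice.

Two caveats are the user's responsibility and are deliberately out of
scope: instruments are assumed approximately independent (no LD clumping
is performed — it needs an external reference panel), and SNP identity is
by rsID alone (no positions, no liftover, no proxy lookup).

## The diagnostic flag

For each analysis the flag is a pure function of the stored estimates and
the level $\alpha$ (default 0.05, reported raw, no multiplicity
correction — the result is a screening heuristic):

* `no_signal` — IVW $p \ge \alpha$;
* `signal_shared_pattern` — IVW significant and the signal is *shared*
  across instruments: at least one of weighted median / weighted mode is
  significant with the IVW sign, or both simply agree with it in sign.
  This is the stratification-like pattern: confounding through population
  structure moves every instrument, so outlier-robust estimators move
  with IVW.
* `signal_outlier_pattern` — IVW significant but contradicted by the
  robust estimators: more consistent with a few pleiotropic outliers than
  with structure.

When fewer than 3 instruments survive, the robust estimators are
unavailable and a significant IVW cannot be decomposed; it is flagged
`signal_shared_pattern` conservatively (investigate). When the outcome
side lacks enough genome-wide-significant SNPs, the outcome-on-control
analysis is reported `not_assessable` instead of failing the run.

## The simulator

`sim_config()` / `make_scenario()` generate the confounding mechanism the
diagnostic targets, so every claim above is testable end-to-end without
any download. The generative model:

* $K$ subpopulations in proportions $\pi_s$; each SNP has an ancestral
  frequency $p_j \sim U(0.1, 0.9)$ and subpopulation frequencies from the
  Balding–Nichols F-model $\mathrm{Beta}(p_j(1-F)/F,\,(1-p_j)(1-F)/F)$,
  which has mean $p_j$ and variance $F\,p_j(1-p_j)$ — the standard
  closed-moment drift model, which is what makes the generator testable.
* dosages $g_{ij} \sim \mathrm{Binomial}(2, p_{j,s(i)})$ (no LD; linkage
  structure is out of scope);
* $X_i = \sum_j \gamma_j g_{ij} + c_X \mu_{s(i)} + \varepsilon_X$,
  $Y_i = \beta X_i + c_Y \mu_{s(i)} + \varepsilon_Y$,
  $NC_i = c_N \mu_{s(i)} + \varepsilon_{NC}$: the negative control has
  **no** genotype, exposure or outcome dependence by construction — it is
  "determined at birth" by the structure alone;
* per-SNP GWAS by OLS with adjustment none / true subpopulation labels /
  top genotype principal components, spanning the adjustment axis real
  studies occupy (mixed models are out of scope);
* two cohorts share one truth (frequencies, effects) but have independent
  genotype and noise streams — the two-sample design, which is why the
  exposure-side and control-side errors are independent under the null.

### Default scale and preset magnitudes

Defaults: $n = 10{,}000$ per cohort, 300 SNPs, 100 causal,
$\gamma_j \sim N(0, 0.15^2)$, $K = 3$ equal subpopulations, $F = 0.05$
(continental-scale differentiation), $\mu = (-1, 0, 1)$, unit residual
SDs. At this scale a typical causal SNP has an association $z$ of about
7, so roughly 40 instruments clear $5\times10^{-8}$ — enough to exercise
every estimator while keeping a full scenario (two cohorts plus three
scans) around a second, and 200-seed calibration studies in minutes.
These sizes are also the ones used by the package's own validation suite
and acceptance script.

The stratification loadings ($c_X = c_Y = c_N = 1$) are artifact choices,
set once so that the confounded per-SNP signal dominates sampling noise
and detection-power properties are stable at this scale; nothing in the
diagnostic depends on their particular values.

The causal preset uses $\beta = 0.1$. Selecting instruments at a fixed
significance threshold leaves the marginal ones at $z \approx 5.5$, which
induces a small multiplicative regression-dilution attenuation of the IVW
estimate (of order $J/\sum_j z_j^2$, here about 2%). The attenuation
scales with $\beta$ while the IVW sampling error does not, so a moderate
effect keeps it second-order; with large simulated effects (or real
exposures with many barely-significant instruments) the same mechanism is
a known, documented source of slight undercoverage.

The pleiotropy preset gives 30% of the causal SNPs a direct effect of
magnitude 0.1 on the negative control with **balanced ± signs**
(InSIDE-satisfying outlier pleiotropy). The balance is a deliberate
design choice: with one-sided contamination at 30% of the weight, the
weighted median targets the $0.5/0.7$ quantile of the valid ratios and is
itself displaced by about half a ratio-SE — no estimator consistent under
the 50%-validity assumption stays centred, and the preset would not
isolate the mechanism it is meant to demonstrate. A
`pleiotropy_directional = TRUE` switch provides the one-sided variant
(every effect oriented along the exposure-increasing allele) for users
who want directional pleiotropy.

### What the simulator does and does not emulate

Passing calibration and detection tests here shows the pipeline behaves
correctly under the modelled mechanism: drift-differentiated independent
SNPs, additive subpopulation mean shifts, OLS scans. Real data add LD
between instruments, assortative mating and family structure, selection
into cohorts, mixed-model association scans, and stratification that is
continuous rather than discrete — none of which the generator reproduces.
Simulation results therefore validate the *software and the logic of the
diagnostic*, not the claim that any particular real GWAS is clean.

## Numerical choices

* Harmonized sets refuse non-positive SEs; missing p-values are
  reconstructed from the two-sided normal tail of $\hat\beta/\mathrm{se}$.
* $\hat\gamma_j = 0$ is a degenerate instrument (error), as is an Egger
  design with all $\hat\gamma_j$ equal after orientation.
* Bootstrap replicates that resample $\hat\gamma_j^*$ near zero produce
  extreme ratios; the median and mode absorb them by construction, and
  the bootstrap SD is reported without trimming.
* The mode's grid argmax takes the smallest grid point on exact ties.
* Balding–Nichols draws are clipped to $[10^{-4}, 1-10^{-4}]$; truly
  monomorphic realized SNPs are marked not assessable and excluded from
  instrument selection.
* Report files print numerics with `%.17g`, so reading them back
  reproduces every stored double bit-for-bit, and repeated renders are
  byte-identical.

## Known limitations

* No LD handling anywhere: clumping must happen upstream, and correlated
  instruments will understate every SE.
* First-order Wald SEs; no NOME/SIMEX-style weak-instrument corrections.
* The shared-vs-outlier flag operationalizes a verbal argument; the exact
  rule is stored with the output so users can re-derive flags under a
  different convention.
* Winner's curse from selecting and estimating $\hat\gamma$ in the same
  sample is present in the simulator exactly as in real single-discovery
  designs; the two-sample layout removes the correlation with the
  control-side errors but not the selection attenuation itself.
* No aggregation across multiple negative controls: disagreeing controls
  are reported side by side, and interpreting the disagreement is left to
  the analyst.
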