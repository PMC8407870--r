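#' Configuration for the stratified-cohort simulator
#'
#' Describes the generative model: `k_subpops` subpopulations whose allele
#' frequencies drift around ancestral values under the Balding-Nichols
#' F-model, a polygenic exposure X with `n_causal` causal SNPs, an outcome
#' Y downstream of X, and a negative-control phenotype NC with no genetic
#' or phenotypic dependence on X or Y. Each subpopulation `s` carries a
#' zero-mean phenotype shift `mu_subpop[s]` that loads onto X, Y and NC
#' with coefficients `strat_x`, `strat_y`, `strat_nc`: when both the
#' allele frequencies and the phenotype means differ across
#' subpopulations, per-SNP association scans are confounded — the
#' population-stratification mechanism the negative-control diagnostic is
#' designed to detect.
#'
#' @param n_individuals cohort size (default 10000).
#' @param n_snps number of SNPs (default 300).
#' @param n_causal SNPs with a true effect on the exposure (default 100).
#' @param k_subpops number of subpopulations (default 3).
#' @param subpop_props mixing proportions, must sum to 1 (default equal).
#' @param fst Balding-Nichols differentiation parameter F in \[0, 1)
#'   (default 0.05).
#' @param anc_freq_range interval for uniform ancestral allele frequencies
#'   (default `c(0.1, 0.9)`).
#' @param gamma_sd SD of the true per-SNP exposure effects (default 0.15,
#'   exposure units per allele).
#' @param beta_xy true causal effect of X on Y (default 0).
#' @param strat_x,strat_y,strat_nc loadings of the subpopulation shift on
#'   X, Y, NC (default 0).
#' @param mu_subpop zero-mean subpopulation shift values; default an
#'   evenly spaced zero-mean sequence from -1 to 1.
#' @param noise_sds residual SDs for X, Y, NC (default `c(1, 1, 1)`).
#' @param pleiotropy_frac fraction of causal SNPs given a direct effect on
#'   the pleiotropy target (default 0).
#' @param pleiotropy_effect magnitude of the per-SNP direct effect; signs
#'   are balanced +/- across the affected SNPs unless
#'   `pleiotropy_directional` is `TRUE`, in which case every effect is
#'   oriented along the SNP's exposure-increasing allele.
#' @param pleiotropy_directional logical, see above (default `FALSE`).
#' @param pleiotropy_target `"nc"` (default) or `"y"`.
#' @param seed RNG seed for the shared truth (allele frequencies, effect
#'   sizes, causal and pleiotropic SNP sets).
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 10000, n_snps = 300, n_causal = 100,
                       k_subpops = 3, subpop_props = NULL, fst = 0.05,
                       anc_freq_range = c(0.1, 0.9), gamma_sd = 0.15,
                       beta_xy = 0, strat_x = 0, strat_y = 0, strat_nc = 0,
                       mu_subpop = NULL, noise_sds = c(1, 1, 1),
                       pleiotropy_frac = 0, pleiotropy_effect = 0,
                       pleiotropy_directional = FALSE,
                       pleiotropy_target = c("nc", "y"), seed = 1) {
  subpop_props <- subpop_props %||% rep(1 / k_subpops, k_subpops)
  mu_subpop <- mu_subpop %||% {
    mu <- if (k_subpops == 1) 0 else seq(-1, 1, length.out = k_subpops)
    mu - mean(mu)
  }
  pleiotropy_target <- match.arg(pleiotropy_target)
  stopifnot(n_individuals >= 1, n_snps >= 1,
            n_causal >= 0, n_causal <= n_snps,
            k_subpops >= 1, length(subpop_props) == k_subpops,
            fst >= 0, fst < 1,
            length(anc_freq_range) == 2,
            anc_freq_range[1] > 0.05, anc_freq_range[2] < 0.95,
            anc_freq_range[1] <= anc_freq_range[2],
            gamma_sd >= 0, length(mu_subpop) == k_subpops,
            length(noise_sds) == 3, all(noise_sds >= 0),
            pleiotropy_frac >= 0, pleiotropy_frac <= 1)
  if (abs(sum(subpop_props) - 1) > 1e-12) {
    stop("subpop_props must sum to 1", call. = FALSE)
  }
  if (abs(mean(mu_subpop)) > 1e-12) {
    stop("mu_subpop must have mean 0", call. = FALSE)
  }
  counts <- diff(round(cumsum(c(0, subpop_props)) * n_individuals))
  if (any(counts == 0)) {
    stop("infeasible config: a subpopulation would have zero members at n = ",
         n_individuals, call. = FALSE)
  }
  structure(list(n_individuals = n_individuals, n_snps = n_snps,
                 n_causal = n_causal, k_subpops = k_subpops,
                 subpop_props = subpop_props, fst = fst,
                 anc_freq_range = anc_freq_range, gamma_sd = gamma_sd,
                 beta_xy = beta_xy, strat_x = strat_x, strat_y = strat_y,
                 strat_nc = strat_nc, mu_subpop = mu_subpop,
                 noise_sds = noise_sds, pleiotropy_frac = pleiotropy_frac,
                 pleiotropy_effect = pleiotropy_effect,
                 pleiotropy_directional = pleiotropy_directional,
                 pleiotropy_target = pleiotropy_target,
                 subpop_counts = counts, seed = seed),
            class = "sim_config")
}

#' Balding-Nichols subpopulation allele frequencies
#'
#' Draws `k` subpopulation frequencies for a SNP with ancestral frequency
#' `p` under the F-model: Beta(p(1-F)/F, (1-p)(1-F)/F), which has mean `p`
#' and variance `F p (1-p)`. `F = 0` returns `p` exactly for every
#' subpopulation. Draws are clipped to `[1e-4, 1 - 1e-4]` to keep every
#' SNP polymorphic in expectation. Vectorized over `p`; uses the current
#' RNG stream, so wrap in a seeded context for reproducibility.
#'
#' @param anc_freq ancestral frequency (vector allowed), each in (0, 1).
#' @param fst differentiation parameter F in \[0, 1).
#' @param k number of subpopulations.
#' @return a `length(anc_freq) x k` matrix of frequencies.
#' @export
draw_subpop_frequencies <- function(anc_freq, fst, k) {
  stopifnot(all(anc_freq > 0), all(anc_freq < 1), fst >= 0, fst < 1, k >= 1)
  m <- length(anc_freq)
  if (fst == 0) {
    return(matrix(anc_freq, nrow = m, ncol = k))
  }
  shape_scale <- (1 - fst) / fst
  draws <- stats::rbeta(m * k, shape1 = rep(anc_freq, k) * shape_scale,
                        shape2 = rep(1 - anc_freq, k) * shape_scale)
  matrix(pmin(pmax(draws, 1e-4), 1 - 1e-4), nrow = m, ncol = k)
}

#' Draw the shared truth of a simulation
#'
#' Realizes everything the two cohorts of a two-sample design must share:
#' ancestral and subpopulation allele frequencies, the causal-SNP set and
#' its effect sizes, and the pleiotropic-SNP set with its direct effects.
#' Driven entirely by `config$seed`.
#'
#' @param config a [sim_config].
#' @return a list of class `sim_truth` with elements `snp` (rsID-like
#'   labels), `anc_freq`, `subpop_freq` (n_snps x k), `gamma` (true
#'   per-SNP exposure effects, 0 off the causal set), `causal` (indices),
#'   `pleio` (indices), `alpha` (per-SNP direct effects on the pleiotropy
#'   target), and `config`.
#' @export
sim_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    m <- config$n_snps
    anc <- stats::runif(m, config$anc_freq_range[1], config$anc_freq_range[2])
    pk <- draw_subpop_frequencies(anc, config$fst, config$k_subpops)
    causal <- sort(sample.int(m, config$n_causal))
    gamma <- numeric(m)
    gamma[causal] <- stats::rnorm(config$n_causal, 0, config$gamma_sd)
    n_pleio <- round(config$pleiotropy_frac * config$n_causal)
    pleio <- if (n_pleio > 0) sort(sample(causal, n_pleio)) else integer()
    alpha <- numeric(m)
    if (n_pleio > 0) {
      sgn <- if (config$pleiotropy_directional) {
        ifelse(gamma[pleio] < 0, -1, 1)
      } else {
        # balanced signs: half +1, half -1, in randomized order
        sample(rep(c(-1, 1), length.out = n_pleio))
      }
      alpha[pleio] <- config$pleiotropy_effect * sgn
    }
    structure(list(snp = sprintf("rs%d", seq_len(m)), anc_freq = anc,
                   subpop_freq = pk, gamma = gamma, causal = causal,
                   pleio = pleio, alpha = alpha, config = config),
              class = "sim_truth")
  })
}

#' Simulate one stratified cohort
#'
#' Draws genotypes and phenotypes for one cohort under a shared truth.
#' Individuals are assigned to subpopulations in the configured
#' proportions; genotype dosages are Binomial(2, p_js) for the
#' individual's subpopulation frequency. Phenotypes follow
#' \deqn{X_i = \sum_j \gamma_j g_{ij} + c_X \mu_{s(i)} + \epsilon_X}
#' \deqn{Y_i = \beta X_i + c_Y \mu_{s(i)} + \epsilon_Y}
#' \deqn{NC_i = c_N \mu_{s(i)} + \epsilon_{NC}}
#' The negative control has no dependence on genotypes, X or Y — it is
#' determined "at birth" by ancestry alone — except under the pleiotropy
#' mechanism, where the affected SNPs add their direct effects
#' `alpha_j g_ij` to the configured target phenotype.
#'
#' @param config a [sim_config].
#' @param truth a [sim_truth]; defaults to `sim_truth(config)`. Pass the
#'   same truth with different `cohort_seed`s to realize independent
#'   cohorts of a two-sample design.
#' @param cohort_seed seed for this cohort's genotype and noise draws;
#'   defaults to `config$seed`.
#' @return a list of class `sim_cohort` with `genotypes` (n x m dosage
#'   matrix), `subpop` (integer labels), `X`, `Y`, `NC`, and `truth`.
#' @export
simulate_cohort <- function(config, truth = NULL, cohort_seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  truth <- truth %||% sim_truth(config)
  cohort_seed <- cohort_seed %||% config$seed
  n <- config$n_individuals
  m <- config$n_snps
  counts <- config$subpop_counts
  subpop <- rep(seq_len(config$k_subpops), counts)
  with_seed(cohort_seed, {
    G <- matrix(0L, nrow = n, ncol = m)
    row0 <- 0L
    for (s in seq_len(config$k_subpops)) {
      ns <- counts[s]
      G[row0 + seq_len(ns), ] <- matrix(
        stats::rbinom(ns * m, 2L, rep(truth$subpop_freq[, s], each = ns)),
        nrow = ns, ncol = m)
      row0 <- row0 + ns
    }
    mu <- config$mu_subpop[subpop]
    X <- drop(G %*% truth$gamma) + config$strat_x * mu +
      stats::rnorm(n, 0, config$noise_sds[1])
    Y <- config$beta_xy * X + config$strat_y * mu +
      stats::rnorm(n, 0, config$noise_sds[2])
    NC <- config$strat_nc * mu + stats::rnorm(n, 0, config$noise_sds[3])
    if (length(truth$pleio)) {
      direct <- drop(G[, truth$pleio, drop = FALSE] %*% truth$alpha[truth$pleio])
      if (config$pleiotropy_target == "nc") NC <- NC + direct
      else Y <- Y + direct
    }
    structure(list(genotypes = G, subpop = subpop, X = X, Y = Y, NC = NC,
                   truth = truth),
              class = "sim_cohort")
  })
}

#' Per-SNP association scan of a simulated cohort
#'
#' Ordinary least squares of the chosen phenotype on each SNP's dosage in
#' turn, with optional stratification adjustment: none, the true
#' subpopulation indicators, or the top principal components of the
#' column-centered genotype matrix. Returns MR-ready summary statistics
#' (beta, SE, two-sided t p-value, observed effect-allele frequency,
#' sample size); alleles are labelled A (effect) / G (other) by
#' convention, so simulated sets harmonize losslessly. Monomorphic SNPs
#' are excluded from the table and listed in the `"not_assessable"`
#' attribute.
#'
#' @param cohort a [sim_cohort].
#' @param phenotype `"X"`, `"Y"` or `"NC"`.
#' @param adjustment `"none"`, `"subpop_labels"` or `"pcs"`.
#' @param n_pcs number of principal components when `adjustment = "pcs"`
#'   (default `k_subpops - 1`).
#' @return a [gwas_records] table.
#' @export
run_gwas <- function(cohort, phenotype = c("X", "Y", "NC"),
                     adjustment = c("none", "subpop_labels", "pcs"),
                     n_pcs = NULL) {
  stopifnot(inherits(cohort, "sim_cohort"))
  phenotype <- match.arg(phenotype)
  adjustment <- match.arg(adjustment)
  y <- cohort[[phenotype]]
  n <- length(y)
  if (stats::sd(y) == 0) {
    stop("constant phenotype: nothing to regress", call. = FALSE)
  }
  G <- cohort$genotypes
  Z <- switch(adjustment,
    none = matrix(1, n, 1),
    subpop_labels = stats::model.matrix(~ factor(cohort$subpop)),
    pcs = {
      k <- n_pcs %||% (cohort$truth$config$k_subpops - 1L)
      stopifnot(k >= 1, k < n)
      pcs <- stats::prcomp(G, center = TRUE, scale. = FALSE, rank. = k)$x
      cbind(1, pcs)
    })
  qz <- qr(Z)
  y_r <- qr.resid(qz, y)
  G_r <- qr.resid(qz, G)
  sxx <- colSums(G_r^2)
  raw_var <- colMeans(G^2) - colMeans(G)^2
  mono <- raw_var == 0 | sxx < 1e-10
  df <- n - ncol(Z) - 1L
  beta <- se <- pval <- rep(NA_real_, ncol(G))
  ok <- !mono
  beta[ok] <- colSums(G_r[, ok, drop = FALSE] * y_r) / sxx[ok]
  rss <- sum(y_r^2) - beta[ok]^2 * sxx[ok]
  rss <- pmax(rss, 0)
  se[ok] <- sqrt(rss / df / sxx[ok])
  tval <- beta[ok] / se[ok]
  pval[ok] <- 2 * stats::pt(-abs(tval), df = df)
  eaf <- colMeans(G) / 2
  records <- gwas_records(
    data.frame(snp = cohort$truth$snp[ok], effect_allele = "A",
               other_allele = "G", eaf = eaf[ok], beta = beta[ok],
               se = se[ok], pval = pval[ok], samplesize = n,
               stringsAsFactors = FALSE),
    phenotype = phenotype)
  attr(records, "not_assessable") <- cohort$truth$snp[mono]
  attr(records, "adjustment") <- adjustment
  records
}

SCENARIO_PRESETS <- list(
  null = list(config = list(fst = 0, beta_xy = 0,
                            strat_x = 0, strat_y = 0, strat_nc = 0),
              adjustment = "none"),
  causal = list(config = list(fst = 0, beta_xy = 0.1,
                              strat_x = 0, strat_y = 0, strat_nc = 0),
                adjustment = "none"),
  stratified = list(config = list(fst = 0.05, beta_xy = 0.2,
                                  strat_x = 1, strat_y = 1, strat_nc = 1),
                    adjustment = "none"),
  stratified_adjusted = list(config = list(fst = 0.05, beta_xy = 0.2,
                                           strat_x = 1, strat_y = 1,
                                           strat_nc = 1),
                             adjustment = "subpop_labels"),
  pleiotropy = list(config = list(fst = 0, beta_xy = 0,
                                  strat_x = 0, strat_y = 0, strat_nc = 0,
                                  pleiotropy_frac = 0.3,
                                  pleiotropy_effect = 0.1),
                    adjustment = "none")
)

#' Generate a complete two-sample scenario
#'
#' Builds the three summary-statistics sets the negative-control pipeline
#' consumes — exposure, outcome, and negative control — from two
#' independent cohorts sharing one truth (allele frequencies and effect
#' sizes), realizing the two-sample design: the exposure GWAS comes from
#' cohort A, the outcome and negative-control GWAS from cohort B.
#'
#' Presets:
#' \describe{
#'   \item{`null`}{no causal effect, no differentiation, no
#'     stratification: everything should be null.}
#'   \item{`causal`}{a moderate true effect of X on Y (`beta_xy = 0.1`)
#'     with an unstructured population; the effect is kept moderate so
#'     that the small multiplicative attenuation from selecting
#'     instruments at the genome-wide threshold stays well below the IVW
#'     sampling error.}
#'   \item{`stratified`}{differentiated subpopulations (F = 0.05) whose
#'     mean shifts load on X, Y and NC; association scans unadjusted, so
#'     every summary set is confounded.}
#'   \item{`stratified_adjusted`}{same generative model, scans adjusted
#'     for the true subpopulation labels.}
#'   \item{`pleiotropy`}{unstructured population; 30% of the causal SNPs
#'     get a direct (balanced-sign) effect of 0.1 on the negative
#'     control.}
#' }
#'
#' @param name preset name.
#' @param overrides named list of [sim_config] arguments overriding the
#'   preset (an `adjustment` entry overrides the scan adjustment).
#' @param seed master seed; the shared truth and the two cohort streams
#'   are derived from it deterministically.
#' @param sets which summary sets to compute (any of `"exposure"`,
#'   `"outcome"`, `"nc"`); skipping unneeded scans speeds up large
#'   repeated-seed studies and does not perturb the RNG streams of the
#'   sets that are kept.
#' @return a list with `exposure`, `outcome`, `nc` ([gwas_records]
#'   tables, `NULL` if not requested), `truth` (a [sim_truth]),
#'   `adjustment`, and `name`.
#' @export
make_scenario <- function(name = c("null", "causal", "stratified",
                                   "stratified_adjusted", "pleiotropy"),
                          overrides = list(), seed = 1,
                          sets = c("exposure", "outcome", "nc")) {
  name <- match.arg(name)
  sets <- match.arg(sets, several.ok = TRUE)
  preset <- SCENARIO_PRESETS[[name]]
  adjustment <- overrides$adjustment %||% preset$adjustment
  overrides$adjustment <- NULL
  args <- utils::modifyList(preset$config, overrides)
  args$seed <- seed
  config <- do.call(sim_config, args)
  truth <- sim_truth(config)
  seeds <- spawn_seeds(seed, 2)
  cohort_a <- simulate_cohort(config, truth, cohort_seed = seeds[1])
  cohort_b <- simulate_cohort(config, truth, cohort_seed = seeds[2])
  scan <- function(cohort, phen, label) {
    g <- run_gwas(cohort, phen, adjustment = adjustment)
    attr(g, "phenotype") <- label
    g
  }
  exposure <- if ("exposure" %in% sets) scan(cohort_a, "X", "exposure")
  outcome <- if ("outcome" %in% sets) scan(cohort_b, "Y", "outcome")
  nc <- if ("nc" %in% sets) scan(cohort_b, "NC", "negative control")
  list(exposure = exposure, outcome = outcome, nc = nc, truth = truth,
       adjustment = adjustment, name = name)
}

#' Write a scenario's summary sets to disk
#'
#' Writes `exposure.tsv`, `outcome.tsv`, `nc.tsv` in the canonical
#' summary-statistics dialect plus `truth.tsv` (per-SNP true effects and
#' memberships) for downstream assertions.
#'
#' @param scenario result of [make_scenario()].
#' @param out_dir output directory, created if absent.
#' @return `out_dir`, invisibly.
#' @export
write_scenario <- function(scenario, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  wr(as.data.frame(scenario$exposure), "exposure.tsv")
  wr(as.data.frame(scenario$outcome), "outcome.tsv")
  wr(as.data.frame(scenario$nc), "nc.tsv")
  truth <- scenario$truth
  m <- length(truth$snp)
  wr(data.frame(snp = truth$snp, anc_freq = truth$anc_freq,
                gamma = truth$gamma,
                causal = seq_len(m) %in% truth$causal,
                pleiotropic = seq_len(m) %in% truth$pleio,
                alpha = truth$alpha, stringsAsFactors = FALSE),
     "truth.tsv")
  invisible(out_dir)
}
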