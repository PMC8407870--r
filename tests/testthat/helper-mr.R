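# Fixture builders and independent oracles used across the suite.

# Random harmonized set with J instruments.
random_hset <- function(J, seed) {
  stopifnot(J >= 1)
  set.seed(seed)
  mrnc:::new_harmonized_set(
    snp = sprintf("rs%d", seq_len(J)),
    beta_exp = rnorm(J, 0, 0.3) + sample(c(-1, 1), J, TRUE) * 0.1,
    se_exp = runif(J, 0.01, 0.05),
    beta_out = rnorm(J, 0, 0.1),
    se_out = runif(J, 0.01, 0.1)
  )
}

# Harmonized set with prescribed ratios: beta_out = ratio * beta_exp,
# se_out chosen so that all per-ratio inverse-variance weights are equal.
hset_from_ratios <- function(ratio, beta_exp = NULL, se_out = NULL) {
  J <- length(ratio)
  beta_exp <- beta_exp %||% seq(0.5, 1.5, length.out = J)
  se_out <- se_out %||% (0.1 * abs(beta_exp))  # ratio_se = 0.1 -> equal weights
  mrnc:::new_harmonized_set(
    snp = sprintf("rs%d", seq_len(J)),
    beta_exp = beta_exp, se_exp = rep(0.01, J),
    beta_out = ratio * beta_exp, se_out = se_out
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Closed-form zero-intercept weighted-least-squares oracle for IVW (fixed).
oracle_ivw_fixed <- function(bx, by, sy) {
  w <- 1 / sy^2
  beta <- sum(w * bx * by) / sum(w * bx^2)
  list(beta = beta, se = 1 / sqrt(sum(w * bx^2)))
}

# Two-parameter weighted normal-equations oracle for MR-Egger, including
# the positive-orientation step and the residual inflation factor.
oracle_egger <- function(bx, by, sy) {
  flip <- ifelse(bx < 0, -1, 1)
  x <- bx * flip; y <- by * flip
  w <- 1 / sy^2
  X <- cbind(1, x)
  XtWX <- t(X) %*% (w * X)
  coefs <- solve(XtWX, t(X) %*% (w * y))
  resid <- y - X %*% coefs
  J <- length(x)
  infl <- max(1, sqrt(sum(w * resid^2) / (J - 2)))
  ses <- unname(sqrt(diag(solve(XtWX)))) * infl
  list(intercept = coefs[1], slope = coefs[2],
       intercept_se = ses[1], slope_se = ses[2])
}

# Brute-force weighted-median oracle: locate the cumulative-weight
# breakpoints by explicit loop and interpolate by hand.
oracle_weighted_median <- function(ratio, weight) {
  o <- order(ratio)
  r <- ratio[o]
  w <- weight[o] / sum(weight)
  p <- numeric(length(w))
  acc <- 0
  for (j in seq_along(w)) {
    p[j] <- acc + w[j] / 2
    acc <- acc + w[j]
  }
  if (0.5 <= p[1]) return(r[1])
  J <- length(p)
  if (0.5 >= p[J]) return(r[J])
  k <- max(which(p <= 0.5))
  r[k] + (0.5 - p[k]) / (p[k + 1] - p[k]) * (r[k + 1] - r[k])
}

# Grid-search weighted-mode oracle at `factor` times the implementation's
# grid resolution, with an independently coded bandwidth and density.
oracle_weighted_mode <- function(ratio, weight, phi = 1, factor = 10) {
  w <- weight / sum(weight)
  s <- sd(ratio)
  m <- mad(ratio, constant = 1) / 0.6745
  spread <- if (m > 0) min(s, m) else s
  h <- phi * 0.9 * spread * length(ratio)^(-1 / 5)
  if (h == 0) return(ratio[1])
  grid <- seq(min(ratio), max(ratio), length.out = 512 * factor)
  dens <- colSums(w * dnorm(outer(ratio, grid, "-") / h))
  grid[which.max(dens)]
}

# Simple-regression coefficients with covariates, via lm() — the oracle
# for the simulated per-SNP association scan.
oracle_snp_ols <- function(y, g, covars = NULL) {
  dat <- if (is.null(covars)) data.frame(y = y, g = g) else {
    cbind(data.frame(y = y, g = g), as.data.frame(covars))
  }
  fit <- lm(y ~ ., data = dat)
  sm <- summary(fit)$coefficients
  list(beta = sm["g", 1], se = sm["g", 2], pval = sm["g", 4])
}

# A tiny deliberately hand-built cohort for run_gwas edge cases.
manual_cohort <- function(G, X, subpop = rep(1L, nrow(G))) {
  cfg <- sim_config(n_individuals = nrow(G), n_snps = ncol(G), n_causal = 0,
                    k_subpops = length(unique(subpop)), seed = 1)
  truth <- list(snp = sprintf("rs%d", seq_len(ncol(G))), config = cfg)
  structure(list(genotypes = G, subpop = subpop, X = X, Y = X, NC = X,
                 truth = truth), class = "sim_cohort")
}

# Write a gwas_records-shaped data.frame to a temp TSV and return the path.
write_sumstats <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# A small well-formed summary table used by several I/O tests.
example_sumstats <- function() {
  data.frame(
    snp = c("rs1", "rs2", "rs3", "rs4"),
    effect_allele = c("A", "C", "G", "T"),
    other_allele = c("G", "T", "A", "C"),
    eaf = c(0.3, 0.6, 0.25, 0.8),
    beta = c(0.10, -0.05, 0.20, 0.02),
    se = c(0.02, 0.01, 0.03, 0.015),
    pval = c(1e-9, 2e-7, 1e-11, 0.2),
    samplesize = 50000,
    stringsAsFactors = FALSE
  )
}
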