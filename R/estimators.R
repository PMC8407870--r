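#' MR estimator results
#'
#' An `mr_estimate` is a one-row summary of a single causal-effect
#' estimator applied to a harmonized instrument set: the method name, the
#' causal-effect estimate `beta` (outcome units per exposure unit), its
#' standard error, two-sided p-value and 95% confidence interval, the
#' number of instruments used, and — for MR-Egger only — the intercept
#' (average directional pleiotropy) with its SE and p-value.
#'
#' @name mr_estimate
NULL

new_mr_estimate <- function(method, beta, se, pval, ci_low, ci_high, n_snps,
                            model_detail = "", intercept = NULL,
                            intercept_se = NULL, intercept_pval = NULL) {
  stopifnot(se >= 0, ci_low <= beta, beta <= ci_high)
  out <- list(method = method, beta = beta, se = se, pval = pval,
              ci_low = ci_low, ci_high = ci_high, n_snps = n_snps,
              model_detail = model_detail)
  if (method == "MR-Egger") {
    out$intercept <- intercept
    out$intercept_se <- intercept_se
    out$intercept_pval <- intercept_pval
  }
  structure(out, class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, digits = 4, ...) {
  cat(sprintf("%s: beta = %.*g (SE %.*g), p = %.3g, 95%% CI [%.*g, %.*g], J = %d\n",
              x$method, digits, x$beta, digits, x$se, x$pval,
              digits, x$ci_low, digits, x$ci_high, x$n_snps))
  if (!is.null(x$intercept)) {
    cat(sprintf("  intercept = %.*g (SE %.*g), p = %.3g\n",
                digits, x$intercept, digits, x$intercept_se, x$intercept_pval))
  }
  invisible(x)
}

#' @export
as.data.frame.mr_estimate <- function(x, ...) {
  data.frame(method = x$method, beta = x$beta, se = x$se, pval = x$pval,
             ci_low = x$ci_low, ci_high = x$ci_high, n_snps = x$n_snps,
             intercept = x$intercept %||% NA_real_,
             intercept_se = x$intercept_se %||% NA_real_,
             intercept_pval = x$intercept_pval %||% NA_real_,
             model_detail = x$model_detail, stringsAsFactors = FALSE)
}

#' Single-SNP Wald ratio
#'
#' The per-SNP causal estimate: SNP-outcome association divided by
#' SNP-exposure association, with the first-order delta-method standard
#' error `se_out / |beta_exp|` (the exposure-side uncertainty term of the
#' second-order expansion is deliberately ignored, the usual
#' summary-data-MR convention).
#'
#' @param beta_exp,se_exp SNP-exposure estimate and SE.
#' @param beta_out,se_out SNP-outcome estimate and SE.
#' @return a list with `ratio` and `ratio_se`.
#' @export
#' @examples
#' wald_ratio(0.5, 0.02, 0.1, 0.05)  # ratio 0.2, SE 0.1
wald_ratio <- function(beta_exp, se_exp, beta_out, se_out) {
  stopifnot(se_exp > 0, se_out > 0)
  if (beta_exp == 0) {
    stop("degenerate instrument: SNP-exposure association is exactly zero",
         call. = FALSE)
  }
  list(ratio = beta_out / beta_exp, ratio_se = se_out / abs(beta_exp))
}

# Per-SNP ratios and normalized inverse-variance weights for a set.
instrument_ratios <- function(hset) {
  if (any(hset$beta_exp == 0)) {
    stop("degenerate instrument: SNP-exposure association is exactly zero",
         call. = FALSE)
  }
  ratio <- hset$beta_out / hset$beta_exp
  ratio_se <- hset$se_out / abs(hset$beta_exp)
  w <- 1 / ratio_se^2
  data.frame(snp = hset$snp, ratio = ratio, ratio_se = ratio_se,
             weight = w / sum(w), stringsAsFactors = FALSE)
}

#' Inverse-variance weighted estimator
#'
#' The IVW estimate is the zero-intercept weighted regression of the
#' SNP-outcome associations on the SNP-exposure associations with weights
#' `1/se_out^2` — equivalently the inverse-variance meta-analysis of the
#' per-SNP Wald ratios. Under the default multiplicative random-effects
#' model the fixed-effect SE is inflated by `max(1, sqrt(Q/(J-1)))`, where
#' Q is Cochran's heterogeneity statistic; p-values use the normal
#' reference. A single-SNP set collapses to the Wald ratio with its
#' first-order SE.
#'
#' @param hset a [harmonized_set].
#' @param model `"mre"` (multiplicative random effects, default) or
#'   `"fixed"`.
#' @return an [mr_estimate].
#' @export
mr_ivw <- function(hset, model = c("mre", "fixed")) {
  stopifnot(inherits(hset, "harmonized_set"))
  model <- match.arg(model)
  J <- n_instruments(hset)
  if (J == 0) stop("empty instrument set", call. = FALSE)
  if (J == 1) {
    wr <- wald_ratio(hset$beta_exp, hset$se_exp, hset$beta_out, hset$se_out)
    beta <- wr$ratio; se <- wr$ratio_se
    p <- z_pvalue(beta, se)
    return(new_mr_estimate("IVW", beta, se, p,
                           beta - stats::qnorm(0.975) * se,
                           beta + stats::qnorm(0.975) * se,
                           1, model_detail = "Wald ratio (single SNP)"))
  }
  w <- 1 / hset$se_out^2
  fit <- stats::lm(beta_out ~ 0 + beta_exp,
                   data = data.frame(beta_out = hset$beta_out,
                                     beta_exp = hset$beta_exp),
                   weights = w)
  beta <- unname(stats::coef(fit)[1])
  se_fixed <- sqrt(summary(fit)$cov.unscaled[1, 1])
  Q <- sum(w * (hset$beta_out - beta * hset$beta_exp)^2)
  se <- if (model == "mre") se_fixed * max(1, sqrt(Q / (J - 1))) else se_fixed
  p <- z_pvalue(beta, se)
  zc <- stats::qnorm(0.975)
  new_mr_estimate("IVW", beta, se, p, beta - zc * se, beta + zc * se, J,
                  model_detail = if (model == "mre") {
                    "multiplicative random effects"
                  } else "fixed effect")
}

#' MR-Egger regression
#'
#' Weighted regression of SNP-outcome on SNP-exposure associations with an
#' intercept, weights `1/se_out^2`. The slope estimates the causal effect
#' under the InSIDE assumption (pleiotropic bias independent of instrument
#' strength); the intercept estimates average directional pleiotropy.
#' Exposure associations are first oriented so every `beta_exp > 0` (both
#' betas of a SNP flipped together), which the intercept's interpretation
#' requires. SEs carry the residual inflation factor
#' `max(1, sqrt(Q'/(J-2)))`; p-values and the CI use the t distribution
#' with J-2 degrees of freedom.
#'
#' @param hset a [harmonized_set] with at least 3 instruments.
#' @return an [mr_estimate] with intercept fields.
#' @export
mr_egger <- function(hset) {
  stopifnot(inherits(hset, "harmonized_set"))
  J <- n_instruments(hset)
  if (J < 3) {
    stop("insufficient instruments for MR-Egger: need J >= 3, have ", J,
         call. = FALSE)
  }
  flip <- ifelse(hset$beta_exp < 0, -1, 1)
  bx <- hset$beta_exp * flip
  by <- hset$beta_out * flip
  if (stats::var(bx) == 0) {
    stop("singular MR-Egger fit: all exposure associations equal after ",
         "orientation", call. = FALSE)
  }
  w <- 1 / hset$se_out^2
  fit <- stats::lm(by ~ bx, weights = w)
  cf <- stats::coef(fit)
  cov_unscaled <- summary(fit)$cov.unscaled
  Qp <- sum(w * stats::resid(fit)^2)
  infl <- max(1, sqrt(Qp / (J - 2)))
  se_slope <- sqrt(cov_unscaled["bx", "bx"]) * infl
  se_int <- sqrt(cov_unscaled["(Intercept)", "(Intercept)"]) * infl
  beta <- unname(cf["bx"]); int <- unname(cf["(Intercept)"])
  tp <- function(est, se) {
    if (se == 0) return(if (est == 0) 1 else 0)
    2 * stats::pt(-abs(est / se), df = J - 2)
  }
  tc <- stats::qt(0.975, df = J - 2)
  new_mr_estimate("MR-Egger", beta, se_slope, tp(beta, se_slope),
                  beta - tc * se_slope, beta + tc * se_slope, J,
                  model_detail = "exposure effects oriented positive; t(J-2) reference",
                  intercept = int, intercept_se = se_int,
                  intercept_pval = tp(int, se_int))
}

# Weighted median of ratios: breakpoint interpolation at cumulative
# weight 1/2, clamped to the extreme ratios.
weighted_median_point <- function(ratio, weight) {
  o <- order(ratio)
  r <- ratio[o]
  w <- weight[o] / sum(weight)
  p <- cumsum(w) - w / 2
  if (0.5 <= p[1]) return(r[1])
  if (0.5 >= p[length(p)]) return(r[length(r)])
  stats::approx(p, r, xout = 0.5, ties = "ordered")$y
}

# Parametric bootstrap SE shared by the median and mode estimators:
# resample both association vectors from their sampling distributions and
# recompute the point estimator.
bootstrap_se <- function(hset, point_fun, n_boot, seed) {
  J <- n_instruments(hset)
  with_seed(seed, {
    reps <- vapply(seq_len(n_boot), function(b) {
      bx <- stats::rnorm(J, hset$beta_exp, hset$se_exp)
      by <- stats::rnorm(J, hset$beta_out, hset$se_out)
      ratio <- by / bx
      ratio_se <- hset$se_out / abs(bx)
      point_fun(ratio, 1 / ratio_se^2)
    }, numeric(1))
    stats::sd(reps)
  })
}

#' Weighted-median estimator
#'
#' The weighted median of the per-SNP Wald ratios with normalized
#' inverse-variance weights: sorted ratios are interpolated at cumulative
#' weight 1/2. Consistent when at least half the weight comes from valid
#' instruments, so robust to a minority of outlying pleiotropic SNPs. The
#' SE comes from a parametric bootstrap that resamples both association
#' vectors from normal sampling distributions; the p-value uses the normal
#' reference.
#'
#' @param hset a [harmonized_set] with at least 3 instruments.
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed RNG seed for the bootstrap; mandatory, no hidden global
#'   state is consumed.
#' @return an [mr_estimate].
#' @export
mr_weighted_median <- function(hset, n_boot = 1000, seed) {
  stopifnot(inherits(hset, "harmonized_set"), n_boot >= 2)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  J <- n_instruments(hset)
  if (J < 3) {
    stop("insufficient instruments for weighted median: need J >= 3, have ",
         J, call. = FALSE)
  }
  ir <- instrument_ratios(hset)
  beta <- weighted_median_point(ir$ratio, ir$weight)
  se <- bootstrap_se(hset, weighted_median_point, n_boot, seed)
  p <- z_pvalue(beta, se)
  zc <- stats::qnorm(0.975)
  new_mr_estimate("Weighted median", beta, se, p,
                  beta - zc * se, beta + zc * se, J,
                  model_detail = sprintf("parametric bootstrap, %d reps", n_boot))
}

# Modified Silverman bandwidth for the ratio density.
mode_bandwidth <- function(ratio, phi) {
  s <- stats::sd(ratio)
  m <- stats::mad(ratio, constant = 1) / 0.6745
  spread <- if (m > 0) min(s, m) else s
  phi * 0.9 * spread * length(ratio)^(-1 / 5)
}

# Weighted-mode point estimator: argmax of the weighted Gaussian kernel
# density over a dense grid spanning the ratio range; ties break to the
# smallest grid point. h = 0 (all ratios identical) returns the common
# ratio.
weighted_mode_point <- function(ratio, weight, phi = 1, grid_n = 512) {
  w <- weight / sum(weight)
  h <- mode_bandwidth(ratio, phi)
  if (h == 0 || diff(range(ratio)) == 0) return(ratio[1])
  grid <- seq(min(ratio), max(ratio), length.out = grid_n)
  dens <- vapply(grid, function(x) sum(w * stats::dnorm((x - ratio) / h)),
                 numeric(1))
  grid[which.max(dens)]
}

#' Weighted-mode estimator
#'
#' The mode of the weighted kernel-density estimate of the per-SNP Wald
#' ratios: Gaussian kernel, modified Silverman bandwidth
#' `phi * 0.9 * min(sd, MAD/0.6745) * J^(-1/5)`, evaluated on a 512-point
#' grid spanning the ratio range (ties break to the smallest grid point).
#' Consistent when the largest group of instruments sharing a ratio is
#' valid. SE by the same parametric bootstrap as [mr_weighted_median()];
#' p-value from the normal reference.
#'
#' @param hset a [harmonized_set] with at least 3 instruments.
#' @param phi bandwidth inflation factor (default 1).
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed RNG seed for the bootstrap; mandatory.
#' @return an [mr_estimate].
#' @export
mr_weighted_mode <- function(hset, phi = 1, n_boot = 1000, seed) {
  stopifnot(inherits(hset, "harmonized_set"), phi > 0, n_boot >= 2)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  J <- n_instruments(hset)
  if (J < 3) {
    stop("insufficient instruments for weighted mode: need J >= 3, have ",
         J, call. = FALSE)
  }
  ir <- instrument_ratios(hset)
  beta <- weighted_mode_point(ir$ratio, ir$weight, phi = phi)
  se <- bootstrap_se(hset,
                     function(r, w) weighted_mode_point(r, w, phi = phi),
                     n_boot, seed)
  p <- z_pvalue(beta, se)
  zc <- stats::qnorm(0.975)
  new_mr_estimate("Weighted mode", beta, se, p,
                  beta - zc * se, beta + zc * se, J,
                  model_detail = sprintf("phi = %g, parametric bootstrap, %d reps",
                                         phi, n_boot))
}
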