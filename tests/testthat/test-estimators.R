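test_that("wald_ratio computes the first-order ratio and SE", {
  wr <- wald_ratio(0.5, 0.02, 0.1, 0.05)
  expect_equal(wr$ratio, 0.2)
  expect_equal(wr$ratio_se, 0.1)
  wr_neg <- wald_ratio(-0.5, 0.02, 0.1, 0.05)
  expect_equal(wr_neg$ratio, -0.2)
  expect_equal(wr_neg$ratio_se, 0.1)
  expect_error(wald_ratio(0, 0.02, 0.1, 0.05), "degenerate instrument")
})

test_that("IVW matches the hand-derived example and collapses at J = 1", {
  h <- mrnc:::new_harmonized_set(c("rs1", "rs2"), c(0.5, 1.0), c(0.02, 0.02),
                                 c(0.15, 0.25), c(0.05, 0.10))
  est <- mr_ivw(h, model = "fixed")
  expect_equal(est$beta, 0.275)           # 55 / 200
  expect_equal(est$se, sqrt(1 / 200))     # 0.070711
  expect_equal(est$ci_low, est$beta - qnorm(0.975) * est$se)

  h1 <- mrnc:::new_harmonized_set("rs1", 0.5, 0.02, 0.1, 0.05)
  est1 <- mr_ivw(h1)
  wr <- wald_ratio(0.5, 0.02, 0.1, 0.05)
  expect_equal(est1$beta, wr$ratio)
  expect_equal(est1$se, wr$ratio_se)

  h0 <- mrnc:::new_harmonized_set(c("a", "b"), c(0.3, 0.6), c(0.02, 0.02),
                                  c(0, 0), c(0.05, 0.05))
  expect_equal(mr_ivw(h0)$beta, 0)
})

test_that("the multiplicative random-effects SE is never below the fixed SE", {
  for (s in 1:40) {
    h <- random_hset(sample(2:30, 1), seed = s)
    expect_gte(mr_ivw(h, "mre")$se, mr_ivw(h, "fixed")$se)
  }
})

test_that("MR-Egger reproduces an exact collinear fit", {
  h <- mrnc:::new_harmonized_set(paste0("rs", 1:3), c(1, 2, 3), rep(0.05, 3),
                                 c(0.3, 0.5, 0.7), c(0.04, 0.02, 0.09))
  est <- suppressWarnings(mr_egger(h))
  expect_equal(est$beta, 0.2)
  expect_equal(est$intercept, 0.1)
  expect_true(!is.null(est$intercept_se))
})

test_that("adding a constant to outcome betas shifts only the Egger intercept", {
  h <- random_hset(8, seed = 9)
  h$beta_exp <- abs(h$beta_exp)  # keep orientation fixed across the pair
  base <- mr_egger(h)
  h2 <- h
  h2$beta_out <- h2$beta_out + 0.3
  shifted <- mr_egger(h2)
  expect_equal(shifted$beta, base$beta)
  expect_equal(shifted$intercept, base$intercept + 0.3)
})

test_that("Egger guards against too few or degenerate instruments", {
  expect_error(mr_egger(random_hset(2, seed = 1)), "insufficient instruments")
  h <- mrnc:::new_harmonized_set(paste0("rs", 1:3), c(0.4, 0.4, -0.4),
                                 rep(0.05, 3), c(0.1, 0.2, 0.15), rep(0.05, 3))
  expect_error(mr_egger(h), "singular")
})

test_that("IVW and Egger agree with normal-equation oracles", {
  for (s in 1:50) {
    h <- random_hset(sample(3:40, 1), seed = 1000 + s)
    o_ivw <- oracle_ivw_fixed(h$beta_exp, h$beta_out, h$se_out)
    est <- mr_ivw(h, "fixed")
    expect_equal(est$beta, o_ivw$beta, tolerance = 1e-10)
    expect_equal(est$se, o_ivw$se, tolerance = 1e-10)
    o_e <- oracle_egger(h$beta_exp, h$beta_out, h$se_out)
    est_e <- mr_egger(h)
    expect_equal(est_e$beta, o_e$slope, tolerance = 1e-10)
    expect_equal(est_e$intercept, o_e$intercept, tolerance = 1e-10)
    expect_equal(est_e$se, o_e$slope_se, tolerance = 1e-10)
    expect_equal(est_e$intercept_se, o_e$intercept_se, tolerance = 1e-10)
  }
})

test_that("weighted median interpolates the cumulative-weight breakpoints", {
  expect_equal(mrnc:::weighted_median_point(c(0.1, 0.2, 0.6), rep(1, 3)), 0.2)
  expect_equal(mrnc:::weighted_median_point(c(0.1, 0.2, 0.4, 0.5), rep(1, 4)), 0.3)
  # a dominant weight pulls the estimate towards that ratio in the limit
  expect_equal(mrnc:::weighted_median_point(c(0.1, 0.2, 0.9),
                                            c(1e-6, 1e-6, 1 - 2e-6)), 0.9,
               tolerance = 1e-5)
  est <- mr_weighted_median(hset_from_ratios(c(0.1, 0.2, 0.4, 0.5)),
                            n_boot = 50, seed = 4)
  expect_equal(est$beta, 0.3)
})

test_that("weighted mode resists an outlying ratio and normalization", {
  h <- hset_from_ratios(c(0.2, 0.21, 0.19, 5.0))
  est <- mr_weighted_mode(h, n_boot = 10, seed = 2)
  expect_lt(abs(est$beta - 0.2), 0.1)
  ir <- mrnc:::instrument_ratios(h)
  expect_equal(mrnc:::weighted_mode_point(ir$ratio, ir$weight),
               mrnc:::weighted_mode_point(ir$ratio, 2 * ir$weight))
  # all ratios identical -> the common ratio
  expect_equal(mrnc:::weighted_mode_point(rep(0.3, 5), rep(1, 5)), 0.3)
})

test_that("median and mode agree with their search oracles", {
  for (s in 1:40) {
    h <- random_hset(sample(3:30, 1), seed = 2000 + s)
    ir <- mrnc:::instrument_ratios(h)
    expect_equal(mrnc:::weighted_median_point(ir$ratio, ir$weight),
                 oracle_weighted_median(ir$ratio, ir$weight),
                 tolerance = 1e-12)
    grid_step <- diff(range(ir$ratio)) / 511
    expect_lt(abs(mrnc:::weighted_mode_point(ir$ratio, ir$weight) -
                    oracle_weighted_mode(ir$ratio, ir$weight)),
              grid_step + 1e-12)
  }
})

test_that("bootstrap SEs are reproducible from the seed", {
  h <- random_hset(10, seed = 77)
  a <- mr_weighted_median(h, n_boot = 200, seed = 123)
  b <- mr_weighted_median(h, n_boot = 200, seed = 123)
  expect_identical(a$se, b$se)
  c_ <- mr_weighted_median(h, n_boot = 200, seed = 124)
  expect_false(identical(a$se, c_$se))
  m1 <- mr_weighted_mode(h, n_boot = 100, seed = 9)
  m2 <- mr_weighted_mode(h, n_boot = 100, seed = 9)
  expect_identical(m1$se, m2$se)
  expect_error(mr_weighted_median(h, n_boot = 100), "`seed` is required")
})

test_that("all estimators are scale- and sign-equivariant in the outcome", {
  for (s in 1:5) {
    h <- random_hset(12, seed = 300 + s)
    ests <- function(hh) list(
      ivw = mr_ivw(hh), egger = mr_egger(hh),
      med = mr_weighted_median(hh, n_boot = 100, seed = 1),
      mode = mr_weighted_mode(hh, n_boot = 50, seed = 2))
    base <- ests(h)
    c_scale <- 2.5
    h_sc <- h
    h_sc$beta_out <- c_scale * h_sc$beta_out
    h_sc$se_out <- c_scale * h_sc$se_out
    scaled <- ests(h_sc)
    h_ng <- h
    h_ng$beta_out <- -h_ng$beta_out
    negated <- ests(h_ng)
    for (k in names(base)) {
      expect_equal(scaled[[k]]$beta, c_scale * base[[k]]$beta,
                   tolerance = 1e-8, label = k)
      expect_equal(scaled[[k]]$se, c_scale * base[[k]]$se,
                   tolerance = 1e-6, label = k)
      expect_equal(negated[[k]]$beta, -base[[k]]$beta,
                   tolerance = 1e-8, label = k)
    }
  }
})

test_that("a minority ratio shift moves IVW but not the weighted median", {
  set.seed(55)
  for (s in 1:5) {
    J <- 20
    ratios <- rnorm(J, 0.3, 0.01)
    shifted <- ratios
    shifted[1:6] <- shifted[1:6] + 2   # 30% of equal ratio weight
    h_shift <- hset_from_ratios(shifted)
    med <- mr_weighted_median(h_shift, n_boot = 100, seed = s)
    expect_lt(abs(med$beta - 0.3), max(2 * med$se, 0.06))
    # with equal ratio weights the IVW is the plain mean of the ratios,
    # so the 30% shift drags it up by ~0.6
    expect_gt(mr_ivw(h_shift, "fixed")$beta - 0.3, 0.4)
    # a shift shared by ALL ratios moves every estimator
    h_all <- hset_from_ratios(ratios + 2)
    expect_gt(mr_ivw(h_all)$beta, 1.5)
    expect_gt(mr_weighted_median(h_all, n_boot = 50, seed = s)$beta, 1.5)
    expect_gt(mr_weighted_mode(h_all, n_boot = 50, seed = s)$beta, 1.5)
    expect_gt(mr_egger(h_all)$beta + mr_egger(h_all)$intercept, 1)
  }
})
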