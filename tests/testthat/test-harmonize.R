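make_pair <- function(exp_df, out_df) {
  list(exposure = gwas_records(exp_df, phenotype = "exp"),
       outcome = gwas_records(out_df, phenotype = "out"))
}

test_that("allele swap and strand complement are resolved", {
  p <- make_pair(
    data.frame(snp = c("rs1", "rs2"), effect_allele = c("A", "C"),
               other_allele = c("G", "A"), eaf = c(0.3, 0.4),
               beta = c(0.10, 0.20), se = c(0.02, 0.02), pval = 1e-9),
    data.frame(snp = c("rs1", "rs2"), effect_allele = c("G", "G"),
               other_allele = c("A", "T"), eaf = c(0.70, 0.41),
               beta = c(-0.05, 0.07), se = c(0.01, 0.01), pval = 0.01)
  )
  h <- harmonize(p$exposure, p$outcome)
  expect_equal(h$snp, c("rs1", "rs2"))
  # rs1: swapped alleles -> beta negated
  expect_equal(h$beta_out[1], 0.05)
  # rs2: exposure C/A vs outcome G/T = complement(C/A) -> direct, kept as-is
  expect_equal(h$beta_out[2], 0.07)
  expect_equal(h$beta_exp, c(0.10, 0.20))
  expect_equal(nrow(h$dropped), 0)
})

test_that("exposure SNPs absent from the outcome are recorded as dropped", {
  p <- make_pair(
    data.frame(snp = c("rs1", "rs9"), effect_allele = "A", other_allele = "G",
               eaf = 0.3, beta = 0.1, se = 0.02, pval = 1e-9),
    data.frame(snp = "rs1", effect_allele = "A", other_allele = "G",
               eaf = 0.3, beta = 0.05, se = 0.01, pval = 0.01)
  )
  h <- harmonize(p$exposure, p$outcome)
  expect_equal(h$snp, "rs1")
  expect_equal(h$dropped$snp, "rs9")
  expect_equal(h$dropped$reason, "not found")
})

test_that("palindromic SNPs follow the frequency policy", {
  exp_df <- data.frame(snp = c("rs1", "rs2", "rs3", "rs4"),
                       effect_allele = c("A", "A", "G", "A"),
                       other_allele = c("T", "T", "C", "T"),
                       eaf = c(0.50, 0.20, 0.30, 0.25),
                       beta = 0.1, se = 0.02, pval = 1e-9)
  out_df <- data.frame(snp = c("rs1", "rs2", "rs3", "rs4"),
                       effect_allele = c("A", "A", "C", "A"),
                       other_allele = c("T", "T", "G", "T"),
                       eaf = c(0.30, 0.22, 0.68, 0.75),
                       beta = c(0.05, 0.05, 0.05, 0.05),
                       se = 0.01, pval = 0.01)
  p <- make_pair(exp_df, out_df)
  h <- harmonize(p$exposure, p$outcome)
  # rs1: exposure eaf = 0.50 sits in the ambiguity band -> dropped
  expect_true("rs1" %in% h$dropped$snp)
  expect_match(h$dropped$reason[h$dropped$snp == "rs1"], "ambiguous")
  # rs2: both frequencies low and concordant -> kept as-is
  expect_equal(h$beta_out[h$snp == "rs2"], 0.05)
  # rs3: labelled swap (G/C vs C/G) flips eaf to 0.32, concordant -> kept negated
  expect_equal(h$beta_out[h$snp == "rs3"], -0.05)
  # rs4: frequencies on opposite sides after orientation -> dropped
  expect_match(h$dropped$reason[h$dropped$snp == "rs4"], "discordant")

  # drop_all on an all-palindromic set leaves nothing to harmonize
  expect_error(harmonize(p$exposure, p$outcome,
                         palindrome_policy = "drop_all"),
               "nothing to harmonize")
  # with one non-palindromic SNP present, drop_all removes the palindromes
  exp5 <- rbind(exp_df, data.frame(snp = "rs5", effect_allele = "A",
                                   other_allele = "G", eaf = 0.3,
                                   beta = 0.1, se = 0.02, pval = 1e-9))
  out5 <- rbind(out_df, data.frame(snp = "rs5", effect_allele = "A",
                                   other_allele = "G", eaf = 0.3,
                                   beta = 0.02, se = 0.01, pval = 0.01))
  p5 <- make_pair(exp5, out5)
  h_all <- harmonize(p5$exposure, p5$outcome, palindrome_policy = "drop_all")
  expect_equal(h_all$snp, "rs5")
  expect_equal(sort(h_all$dropped$snp), c("rs1", "rs2", "rs3", "rs4"))
  expect_true(all(grepl("drop_all", h_all$dropped$reason)))
})

test_that("missing frequency makes a palindrome ambiguous", {
  p <- make_pair(
    data.frame(snp = "rs1", effect_allele = "A", other_allele = "T",
               eaf = NA, beta = 0.1, se = 0.02, pval = 1e-9),
    data.frame(snp = c("rs1", "rs2"), effect_allele = c("A", "A"),
               other_allele = c("T", "G"),
               eaf = 0.2, beta = 0.05, se = 0.01, pval = 0.01)
  )
  expect_error(harmonize(p$exposure, p$outcome), "nothing to harmonize")
})

test_that("the effect-allele flip is an involution", {
  set.seed(11)
  for (s in 1:20) {
    df <- example_sumstats()
    df$beta <- rnorm(4)
    df$eaf <- runif(4)
    rec <- gwas_records(df)
    expect_equal(as.data.frame(flip_effect_allele(flip_effect_allele(rec))),
                 as.data.frame(rec))
  }
})

test_that("harmonization is invariant to the outcome file's orientation", {
  set.seed(3)
  exp_df <- data.frame(snp = sprintf("rs%d", 1:8),
                       effect_allele = rep(c("A", "C"), 4),
                       other_allele = rep(c("G", "T"), 4),
                       eaf = runif(8, 0.1, 0.45),
                       beta = rnorm(8, 0, 0.2), se = runif(8, 0.01, 0.05),
                       pval = 1e-9)
  out_df <- exp_df
  out_df$beta <- rnorm(8, 0, 0.1)
  out_df$se <- runif(8, 0.01, 0.05)
  out_df$pval <- 0.05
  p <- make_pair(exp_df, out_df)
  h1 <- harmonize(p$exposure, p$outcome)
  flipped <- flip_effect_allele(gwas_records(out_df, phenotype = "out"))
  h2 <- harmonize(p$exposure, flipped)
  expect_equal(h1$snp, h2$snp)
  expect_equal(h1$beta_out, h2$beta_out)
  expect_equal(h1$se_out, h2$se_out)
})

test_that("harmonized sets round-trip through disk bit-for-bit", {
  h <- random_hset(7, seed = 21)
  h$dropped <- data.frame(snp = "rs99", reason = "not found",
                          stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".tsv")
  write_harmonized(h, path)
  back <- read_harmonized(path)
  expect_identical(back$beta_exp, h$beta_exp)
  expect_identical(back$se_exp, h$se_exp)
  expect_identical(back$beta_out, h$beta_out)
  expect_identical(back$se_out, h$se_out)
  expect_equal(back$dropped, h$dropped)

  # J = 1 set -> one data row; empty dropped list -> header-only sidecar
  h1 <- random_hset(1, seed = 5)
  path1 <- tempfile(fileext = ".tsv")
  write_harmonized(h1, path1)
  expect_equal(length(readLines(path1)), 2)
  sidecar <- sub("\\.tsv$", "_dropped.tsv", path1)
  expect_equal(length(readLines(sidecar)), 1)
})
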