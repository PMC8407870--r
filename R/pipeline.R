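#' Analysis configuration
#'
#' Bundles the run parameters shared across the pipeline: instrument
#' selection threshold and minimum count, palindrome policy and frequency
#' window for harmonization, IVW variant, bootstrap settings for the
#' weighted median/mode, bandwidth factor, flagging level, and the master
#' seed every stochastic step derives its stream from.
#'
#' @param p_threshold instrument p-value threshold (default `5e-8`).
#' @param min_count minimum instrument count (default 5).
#' @param palindrome_policy `"drop_ambiguous"` or `"drop_all"`.
#' @param eaf_window palindrome frequency half-width (default 0.08).
#' @param ivw_model `"mre"` or `"fixed"`.
#' @param n_boot bootstrap replicates for median/mode SEs (default 1000).
#' @param phi weighted-mode bandwidth factor (default 1).
#' @param alpha flagging level for the diagnostic (default 0.05).
#' @param seed master RNG seed (default 1).
#' @return a list of class `mr_config`.
#' @export
mr_config <- function(p_threshold = 5e-8, min_count = 5,
                      palindrome_policy = "drop_ambiguous", eaf_window = 0.08,
                      ivw_model = "mre", n_boot = 1000, phi = 1,
                      alpha = 0.05, seed = 1) {
  structure(list(p_threshold = p_threshold, min_count = min_count,
                 palindrome_policy = palindrome_policy,
                 eaf_window = eaf_window, ivw_model = ivw_model,
                 n_boot = n_boot, phi = phi, alpha = alpha, seed = seed),
            class = "mr_config")
}

#' Run the full MR estimator suite for one exposure/outcome pair
#'
#' Selects genome-wide-significant instruments from the exposure summary
#' statistics, harmonizes them against the outcome, and computes the IVW
#' estimate plus — when at least 3 instruments survive — the MR-Egger,
#' weighted-median and weighted-mode sensitivity estimates. The result is
#' deterministic given the inputs, config and seed.
#'
#' @param exposure_records,outcome_records [gwas_records] tables.
#' @param config an [mr_config].
#' @return an `mr_result_set`: list with `exposure`, `outcome`,
#'   `estimates` (named list of [mr_estimate]s, `"IVW"` always present),
#'   `j_used`, and `dropped_summary` (drop counts by reason).
#' @export
run_mr_suite <- function(exposure_records, outcome_records,
                         config = mr_config()) {
  exposure_label <- attr(exposure_records, "phenotype") %||% "exposure"
  instruments <- tryCatch(
    select_instruments(exposure_records, config$p_threshold, config$min_count),
    error = function(e) {
      stop("[", exposure_label, "] ", conditionMessage(e), call. = FALSE)
    })
  hset <- tryCatch(
    harmonize(instruments, outcome_records,
              palindrome_policy = config$palindrome_policy,
              eaf_window = config$eaf_window),
    error = function(e) {
      stop("[", exposure_label, "] ", conditionMessage(e), call. = FALSE)
    })
  J <- n_instruments(hset)
  estimates <- list(IVW = mr_ivw(hset, model = config$ivw_model))
  if (J >= 3) {
    seeds <- spawn_seeds(config$seed, 2)
    estimates[["MR-Egger"]] <- mr_egger(hset)
    estimates[["Weighted median"]] <-
      mr_weighted_median(hset, n_boot = config$n_boot, seed = seeds[1])
    estimates[["Weighted mode"]] <-
      mr_weighted_mode(hset, phi = config$phi, n_boot = config$n_boot,
                       seed = seeds[2])
  } else {
    message("run_mr_suite: J = ", J,
            " < 3; skipping MR-Egger, weighted median and weighted mode")
  }
  dropped_summary <- if (nrow(hset$dropped)) {
    table(hset$dropped$reason)
  } else table(character())
  structure(list(exposure = hset$exposure, outcome = hset$outcome,
                 estimates = estimates, j_used = J,
                 dropped_summary = dropped_summary, hset = hset),
            class = "mr_result_set")
}

#' @export
print.mr_result_set <- function(x, ...) {
  cat("<mr_result_set> ", x$exposure, " -> ", x$outcome,
      " (J = ", x$j_used, ")\n", sep = "")
  for (est in x$estimates) print(est, ...)
  invisible(x)
}

#' Classify an MR result as stratification-like, outlier-like, or null
#'
#' Implements the diagnostic reading of a negative-control MR result:
#' confounding by population stratification acts on every instrument, so
#' a stratification signal survives the outlier-robust weighted-median and
#' weighted-mode estimators, whereas pleiotropy confined to a few SNPs
#' does not.
#'
#' The rule: `no_signal` if the IVW p-value is at least `alpha`;
#' otherwise `signal_shared_pattern` when at least one of weighted median
#' / weighted mode is significant at `alpha` with the IVW sign, or when
#' both share the IVW sign (direction consistency); otherwise
#' `signal_outlier_pattern`. If the sensitivity estimators are unavailable
#' (J < 3) a significant IVW cannot be decomposed and is conservatively
#' flagged `signal_shared_pattern`. The flag is a screening heuristic
#' ("warrants further investigation"), not a hard hypothesis test.
#'
#' @param result_set an `mr_result_set` from [run_mr_suite()].
#' @param alpha flagging level (default 0.05).
#' @return one of `"no_signal"`, `"signal_shared_pattern"`,
#'   `"signal_outlier_pattern"`.
#' @export
flag_stratification <- function(result_set, alpha = 0.05) {
  stopifnot(inherits(result_set, "mr_result_set"), "IVW" %in% names(result_set$estimates))
  ivw <- result_set$estimates[["IVW"]]
  if (is.na(ivw$pval) || ivw$pval >= alpha) return("no_signal")
  med <- result_set$estimates[["Weighted median"]]
  mode <- result_set$estimates[["Weighted mode"]]
  if (is.null(med) || is.null(mode)) return("signal_shared_pattern")
  s <- sign(ivw$beta)
  robust_sig <- (sign(med$beta) == s && med$pval < alpha) ||
    (sign(mode$beta) == s && mode$pval < alpha)
  both_same_sign <- sign(med$beta) == s && sign(mode$beta) == s
  if (robust_sig || both_same_sign) "signal_shared_pattern"
  else "signal_outlier_pattern"
}

#' Run the negative-control-outcome diagnostic
#'
#' For each supplied negative-control summary set, runs the two
#' sensitivity analyses of the negative-control procedure:
#' \enumerate{
#'   \item MR of the exposure of interest on the negative control
#'     (`exposure_on_nc`);
#'   \item MR of the outcome of interest on the negative control
#'     (`outcome_on_nc`), the outcome's own genome-wide-significant SNPs
#'     serving as instruments.
#' }
#' A negative control is a phenotype largely determined before the
#' exposure and outcome (e.g. tanning ability, hair colour) that cannot be
#' causally downstream of them but shares their confounding structure: any
#' MR "effect" on it signals instrument-outcome confounding such as
#' residual population stratification. Each analysis is flagged via
#' [flag_stratification()]. When the outcome lacks enough
#' genome-wide-significant SNPs, analysis (2) is reported as not
#' assessable rather than failing the run. The choice of negative control
#' is the caller's responsibility; nothing here validates that it is
#' genuinely predetermined.
#'
#' @param exposure_records,outcome_records [gwas_records] tables.
#' @param nc_records_list one [gwas_records] table or a list of them, one
#'   per negative-control outcome.
#' @param config an [mr_config].
#' @return an `nc_report`: list with `triples` (each holding
#'   `analysis_role`, `negative_control`, `result` or `NULL`, `flag`,
#'   `note`), `alpha`, and `config`.
#' @export
run_negative_control_analysis <- function(exposure_records, outcome_records,
                                          nc_records_list,
                                          config = mr_config()) {
  if (inherits(nc_records_list, "gwas_records")) {
    nc_records_list <- list(nc_records_list)
  }
  if (!length(nc_records_list)) {
    stop("at least one negative-control summary set is required",
         call. = FALSE)
  }
  triples <- list()
  for (nc in nc_records_list) {
    nc_label <- attr(nc, "phenotype") %||% "negative control"
    rs_a <- run_mr_suite(exposure_records, nc, config)
    triples[[length(triples) + 1L]] <- list(
      analysis_role = "exposure_on_nc", negative_control = nc_label,
      result = rs_a, flag = flag_stratification(rs_a, config$alpha),
      note = "")
    rs_b <- tryCatch(run_mr_suite(outcome_records, nc, config),
                     error = function(e) conditionMessage(e))
    if (is.character(rs_b)) {
      triples[[length(triples) + 1L]] <- list(
        analysis_role = "outcome_on_nc", negative_control = nc_label,
        result = NULL, flag = "not_assessable", note = rs_b)
    } else {
      triples[[length(triples) + 1L]] <- list(
        analysis_role = "outcome_on_nc", negative_control = nc_label,
        result = rs_b, flag = flag_stratification(rs_b, config$alpha),
        note = "")
    }
  }
  structure(list(triples = triples, alpha = config$alpha, config = config),
            class = "nc_report")
}

#' @export
print.nc_report <- function(x, ...) {
  cat("<nc_report> ", length(x$triples), " analysis/analyses, alpha = ",
      x$alpha, "\n", sep = "")
  for (tr in x$triples) {
    lab <- if (is.null(tr$result)) "(not assessable)" else {
      sprintf("%s -> %s", tr$result$exposure, tr$result$outcome)
    }
    cat(sprintf("  [%s] %s : %s\n", tr$analysis_role, lab, tr$flag))
  }
  invisible(x)
}

result_set_rows_empty <- function() {
  data.frame(exposure = character(), outcome = character(),
             n_snps = integer(), method = character(), beta = numeric(),
             se = numeric(), pval = numeric(), ci_low = numeric(),
             ci_high = numeric(), intercept = numeric(),
             intercept_se = numeric(), intercept_pval = numeric(),
             model_detail = character(), analysis_role = character(),
             stringsAsFactors = FALSE)
}

# Flatten a result set into the report-table layout.
result_set_rows <- function(rs) {
  rows <- lapply(rs$estimates, as.data.frame)
  df <- do.call(rbind, rows)
  df <- data.frame(exposure = rs$exposure, outcome = rs$outcome,
                   n_snps = rs$j_used, df, row.names = NULL,
                   stringsAsFactors = FALSE)
  df
}

#' Write the diagnostic report to disk
#'
#' Writes three TSVs to `out_dir`: `report.tsv` with one row per
#' estimator in the classical results-table layout (exposure, number of
#' SNPs, estimation method, effect, standard error, p-value, 95% CI);
#' `forest.tsv` with label / beta / ci_low / ci_high rows ready for a
#' forest plot; and `flags.tsv` with one diagnostic flag per analysis.
#' Output bytes are deterministic given a fixed report.
#'
#' @param report an `nc_report`.
#' @param out_dir output directory, created if absent.
#' @return `out_dir`, invisibly.
#' @export
render_report <- function(report, out_dir) {
  stopifnot(inherits(report, "nc_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  fmt <- function(x) ifelse(is.na(x), "NA", sprintf("%.17g", x))
  report_rows <- list(); forest_rows <- list(); flag_rows <- list()
  for (tr in report$triples) {
    flag_rows[[length(flag_rows) + 1L]] <- data.frame(
      analysis_role = tr$analysis_role,
      negative_control = tr$negative_control,
      flag = tr$flag, alpha = report$alpha, note = tr$note,
      stringsAsFactors = FALSE)
    if (is.null(tr$result)) next
    df <- result_set_rows(tr$result)
    df$analysis_role <- tr$analysis_role
    report_rows[[length(report_rows) + 1L]] <- df
    forest_rows[[length(forest_rows) + 1L]] <- data.frame(
      label = sprintf("%s -> %s [%s]", df$exposure, df$outcome, df$method),
      beta = df$beta, ci_low = df$ci_low, ci_high = df$ci_high,
      stringsAsFactors = FALSE)
  }
  rep_df <- do.call(rbind, report_rows)
  if (is.null(rep_df)) {
    rep_df <- result_set_rows_empty()
  }
  main <- data.frame(
    Exposure = rep_df$exposure, Outcome = rep_df$outcome,
    Analysis = rep_df$analysis_role, No.SNPs = rep_df$n_snps,
    Est.method = rep_df$method, Effect = fmt(rep_df$beta),
    Std.error = fmt(rep_df$se), P.value = fmt(rep_df$pval),
    CI.low = fmt(rep_df$ci_low), CI.high = fmt(rep_df$ci_high),
    Intercept = fmt(rep_df$intercept), Model = rep_df$model_detail,
    stringsAsFactors = FALSE, check.names = FALSE)
  utils::write.table(main, file.path(out_dir, "report.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  forest <- do.call(rbind, forest_rows) %||%
    data.frame(label = character(), beta = numeric(), ci_low = numeric(),
               ci_high = numeric(), stringsAsFactors = FALSE)
  forest$beta <- fmt(forest$beta)
  forest$ci_low <- fmt(forest$ci_low)
  forest$ci_high <- fmt(forest$ci_high)
  utils::write.table(forest, file.path(out_dir, "forest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(do.call(rbind, flag_rows),
                     file.path(out_dir, "flags.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}
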