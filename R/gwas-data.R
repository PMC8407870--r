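#' GWAS summary-statistic tables
#'
#' A `gwas_records` object is a plain `data.frame` with one row per SNP and
#' the canonical columns `snp`, `effect_allele`, `other_allele`, `eaf`,
#' `beta`, `se`, `pval`, `samplesize`. Rows hold per-allele association
#' estimates of a single phenotype, in the usual two-sample MR convention:
#' `beta` is the phenotype change per copy of `effect_allele` and `eaf` is
#' the effect-allele frequency. `eaf` and `samplesize` may be `NA`;
#' everything used in estimation must have `se > 0`.
#'
#' @name gwas_records
NULL

CANONICAL_COLUMNS <- c("snp", "effect_allele", "other_allele", "eaf",
                       "beta", "se", "pval", "samplesize")
VALID_BASES <- c("A", "C", "G", "T")

#' Construct and validate a GWAS summary table
#'
#' @param df data.frame carrying at least `snp`, `effect_allele`,
#'   `other_allele`, `beta`, `se`; `eaf`, `pval` and `samplesize` are
#'   optional (`pval` is reconstructed from `beta/se` when missing).
#' @param phenotype optional label stored as the `"phenotype"` attribute.
#' @return a validated `gwas_records` data.frame with the canonical columns.
#' @export
#' @examples
#' gwas_records(data.frame(snp = "rs1", effect_allele = "A",
#'                         other_allele = "G", eaf = 0.3,
#'                         beta = 0.1, se = 0.02))
gwas_records <- function(df, phenotype = NULL) {
  stopifnot(is.data.frame(df))
  need <- c("snp", "effect_allele", "other_allele", "beta", "se")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  out <- data.frame(
    snp           = as.character(df$snp),
    effect_allele = toupper(as.character(df$effect_allele)),
    other_allele  = toupper(as.character(df$other_allele)),
    eaf           = if ("eaf" %in% names(df)) as.numeric(df$eaf) else NA_real_,
    beta          = as.numeric(df$beta),
    se            = as.numeric(df$se),
    pval          = if ("pval" %in% names(df)) as.numeric(df$pval) else NA_real_,
    samplesize    = if ("samplesize" %in% names(df))
                      as.numeric(df$samplesize) else NA_real_,
    stringsAsFactors = FALSE
  )
  # missing p reconstructed as the two-sided normal tail of beta/se
  miss_p <- is.na(out$pval) & is.finite(out$beta) & is.finite(out$se) & out$se > 0
  out$pval[miss_p] <- 2 * stats::pnorm(-abs(out$beta[miss_p] / out$se[miss_p]))
  bad <- !(out$effect_allele %in% VALID_BASES) |
    !(out$other_allele %in% VALID_BASES) |
    out$effect_allele == out$other_allele
  if (any(bad)) {
    stop("invalid alleles for SNP(s): ",
         paste(utils::head(out$snp[bad], 5), collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(out$se) | out$se <= 0)) {
    stop("standard errors must be finite and > 0", call. = FALSE)
  }
  attr(out, "phenotype") <- phenotype
  class(out) <- c("gwas_records", "data.frame")
  out
}

#' Read GWAS summary statistics from a delimited text file
#'
#' Reads a tab- or comma-delimited summary-statistics file with a header
#' row into a [gwas_records] table. Rows with malformed alleles (indels,
#' non-ACGT codes, identical alleles), non-positive or unparseable standard
#' errors, or unparseable betas are skipped; the skip count is reported via
#' `message()` and stored in the `"n_skipped"` attribute.
#'
#' @param path path to the file.
#' @param column_map named character vector mapping canonical field names
#'   (`snp`, `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`,
#'   `samplesize`) to the file's actual headers. Defaults to the identity
#'   map; only the mapped-and-present columns are used.
#' @param delim field delimiter; `NULL` (default) auto-detects tab vs comma
#'   from the header line.
#' @param phenotype optional phenotype label attached to the result.
#' @return a [gwas_records] data.frame.
#' @export
read_summary_stats <- function(path, column_map = NULL, delim = NULL,
                               phenotype = NULL) {
  if (!file.exists(path)) {
    stop("summary-statistics file not found: ", path, call. = FALSE)
  }
  if (is.null(delim)) {
    header <- readLines(path, n = 1L)
    delim <- if (grepl("\t", header)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = delim,
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "", check.names = FALSE)
  map <- stats::setNames(CANONICAL_COLUMNS, CANONICAL_COLUMNS)
  if (!is.null(column_map)) {
    unknown <- setdiff(names(column_map), CANONICAL_COLUMNS)
    if (length(unknown)) {
      stop("column_map refers to unknown canonical field(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    map[names(column_map)] <- unname(column_map)
  }
  present <- map[map %in% names(raw)]
  need <- c("snp", "effect_allele", "other_allele", "beta", "se")
  if (!all(need %in% names(present))) {
    stop("file ", path, " lacks required column(s): ",
         paste(setdiff(need, names(present)), collapse = ", "), call. = FALSE)
  }
  df <- raw[unname(present)]
  names(df) <- names(present)

  as_num <- function(x) suppressWarnings(as.numeric(x))
  ea <- toupper(as.character(df$effect_allele))
  oa <- toupper(as.character(df$other_allele))
  beta <- as_num(df$beta)
  se <- as_num(df$se)
  keep <- ea %in% VALID_BASES & oa %in% VALID_BASES & ea != oa &
    is.finite(beta) & is.finite(se) & se > 0
  n_skipped <- sum(!keep)
  if (n_skipped > 0) {
    message("read_summary_stats: skipped ", n_skipped, " malformed row(s) in ",
            basename(path))
  }
  if (!any(keep)) {
    stop("no parseable rows in ", path, call. = FALSE)
  }
  df <- df[keep, , drop = FALSE]
  df$beta <- as_num(df$beta)
  df$se <- as_num(df$se)
  for (col in intersect(c("eaf", "pval", "samplesize"), names(df))) {
    df[[col]] <- as_num(df[[col]])
  }
  out <- gwas_records(df, phenotype = phenotype)
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Select genome-wide-significant instruments
#'
#' Keeps records with `pval < p_threshold`, de-duplicating repeated rsIDs
#' by smallest p-value and preserving input order among survivors. Errors
#' when fewer than `min_count` instruments survive, mirroring the standard
#' practice of excluding exposures with too few genome-wide-significant
#' SNPs from two-sample MR.
#'
#' @param records a [gwas_records] table for the exposure.
#' @param p_threshold significance threshold; default `5e-8`, the
#'   genome-wide significance convention.
#' @param min_count minimum acceptable number of instruments (default 5).
#' @return the selected subset, a [gwas_records] table.
#' @export
select_instruments <- function(records, p_threshold = 5e-8, min_count = 5) {
  stopifnot(inherits(records, "gwas_records"),
            is.numeric(p_threshold), p_threshold > 0, p_threshold < 1)
  keep <- !is.na(records$pval) & records$pval < p_threshold
  out <- records[keep, , drop = FALSE]
  if (anyDuplicated(out$snp)) {
    # smallest p-value wins; order() is stable so input order breaks ties
    best <- tapply(seq_len(nrow(out)), out$snp, function(i) {
      i[which.min(out$pval[i])]
    })
    out <- out[sort(unlist(best, use.names = FALSE)), , drop = FALSE]
  }
  if (nrow(out) < min_count) {
    stop("insufficient instruments: found ", nrow(out),
         " genome-wide significant SNP(s), need at least ", min_count,
         call. = FALSE)
  }
  rownames(out) <- NULL
  class(out) <- c("gwas_records", "data.frame")
  attr(out, "phenotype") <- attr(records, "phenotype")
  out
}
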