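#' Harmonized instrument sets
#'
#' A `harmonized_set` holds per-SNP exposure/outcome association pairs
#' expressed on a common effect allele: the SNP-exposure estimates
#' (`beta_exp`, `se_exp`) and the SNP-outcome estimates (`beta_out`,
#' `se_out`) for the same J instruments, plus a `dropped` table recording
#' every exposure instrument removed during harmonization and why.
#'
#' @name harmonized_set
NULL

COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

is_palindromic <- function(a1, a2) COMPLEMENT[a1] == a2

new_harmonized_set <- function(snp, beta_exp, se_exp, beta_out, se_out,
                               exposure = "exposure", outcome = "outcome",
                               dropped = NULL) {
  J <- length(snp)
  stopifnot(J >= 1,
            length(beta_exp) == J, length(se_exp) == J,
            length(beta_out) == J, length(se_out) == J,
            all(se_exp > 0), all(se_out > 0),
            !anyDuplicated(snp))
  dropped <- dropped %||%
    data.frame(snp = character(), reason = character(),
               stringsAsFactors = FALSE)
  if (any(dropped$snp %in% snp)) {
    stop("a SNP cannot be both retained and dropped", call. = FALSE)
  }
  structure(
    list(snp = as.character(snp),
         beta_exp = as.numeric(beta_exp), se_exp = as.numeric(se_exp),
         beta_out = as.numeric(beta_out), se_out = as.numeric(se_out),
         exposure = exposure, outcome = outcome, dropped = dropped),
    class = "harmonized_set"
  )
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat("<harmonized_set> ", x$exposure, " -> ", x$outcome, "\n", sep = "")
  cat("  ", length(x$snp), " instrument(s), ", nrow(x$dropped),
      " dropped\n", sep = "")
  invisible(x)
}

#' Number of instruments in a harmonized set
#' @param hset a [harmonized_set].
#' @return integer instrument count J.
#' @export
n_instruments <- function(hset) length(hset$snp)

#' Harmonize exposure instruments against outcome summary statistics
#'
#' Aligns each exposure instrument with the outcome record carrying the
#' same rsID so that both association estimates refer to the same effect
#' allele. Allele matching proceeds in order: identical alleles are kept
#' as-is; swapped alleles flip the outcome beta's sign and replace the
#' outcome `eaf` by `1 - eaf`; alleles that only match after strand
#' complement (A<->T, C<->G) are complemented first. Palindromic SNPs
#' (A/T or G/C pairs), for which the strand cannot be resolved from
#' alleles alone, are handled by `palindrome_policy`:
#' \describe{
#'   \item{`"drop_ambiguous"`}{(default) keep a palindromic pair only when
#'     both allele frequencies are available, both fall outside the
#'     ambiguity band `0.5 +/- eaf_window`, and the frequencies agree with
#'     the label-based orientation (same side of 0.5 after any swap);
#'     otherwise drop with a recorded reason.}
#'   \item{`"drop_all"`}{always drop palindromic SNPs.}
#' }
#' Exposure SNPs absent from the outcome are recorded as dropped with
#' reason `"not found"`. SNP identity is by rsID only; positions and
#' strand annotations are ignored, and instruments are assumed to be
#' approximately independent (LD clumping is out of scope and must happen
#' upstream).
#'
#' @param exposure_instruments [gwas_records] of selected instruments.
#' @param outcome_records [gwas_records] for the outcome phenotype.
#' @param palindrome_policy `"drop_ambiguous"` or `"drop_all"`.
#' @param eaf_window half-width of the frequency ambiguity band around 0.5
#'   (default 0.08, i.e. drop when either eaf lies in 0.42-0.58).
#' @return a [harmonized_set].
#' @export
harmonize <- function(exposure_instruments, outcome_records,
                      palindrome_policy = c("drop_ambiguous", "drop_all"),
                      eaf_window = 0.08) {
  stopifnot(inherits(exposure_instruments, "gwas_records"),
            inherits(outcome_records, "gwas_records"),
            nrow(exposure_instruments) >= 1, nrow(outcome_records) >= 1,
            is.numeric(eaf_window), eaf_window >= 0, eaf_window < 0.5)
  palindrome_policy <- match.arg(palindrome_policy)

  idx <- match(exposure_instruments$snp, outcome_records$snp)
  keep_snp <- character(); bx <- numeric(); sx <- numeric()
  by <- numeric(); sy <- numeric()
  drop_snp <- character(); drop_reason <- character()
  drop <- function(snp, reason) {
    drop_snp <<- c(drop_snp, snp); drop_reason <<- c(drop_reason, reason)
  }

  for (i in seq_len(nrow(exposure_instruments))) {
    e <- exposure_instruments[i, ]
    if (is.na(idx[i])) { drop(e$snp, "not found"); next }
    o <- outcome_records[idx[i], ]

    if (is_palindromic(e$effect_allele, e$other_allele)) {
      if (palindrome_policy == "drop_all") {
        drop(e$snp, "palindromic, policy drop_all"); next
      }
      # orientation by label first (complement is a no-op for palindromes),
      # then require both frequencies to confirm it
      if (o$effect_allele == e$effect_allele && o$other_allele == e$other_allele) {
        flip <- FALSE
      } else if (o$effect_allele == e$other_allele && o$other_allele == e$effect_allele) {
        flip <- TRUE
      } else {
        drop(e$snp, "allele mismatch"); next
      }
      eaf_o <- if (flip) 1 - o$eaf else o$eaf
      if (is.na(e$eaf) || is.na(eaf_o)) {
        drop(e$snp, "palindromic, ambiguous frequency"); next
      }
      inside_band <- function(f) abs(f - 0.5) <= eaf_window
      if (inside_band(e$eaf) || inside_band(eaf_o)) {
        drop(e$snp, "palindromic, ambiguous frequency"); next
      }
      if (sign(e$eaf - 0.5) != sign(eaf_o - 0.5)) {
        drop(e$snp, "palindromic, discordant frequency"); next
      }
      keep_snp <- c(keep_snp, e$snp)
      bx <- c(bx, e$beta); sx <- c(sx, e$se)
      by <- c(by, if (flip) -o$beta else o$beta); sy <- c(sy, o$se)
      next
    }

    o_ea <- o$effect_allele; o_oa <- o$other_allele
    direct <- o_ea == e$effect_allele && o_oa == e$other_allele
    swapped <- o_ea == e$other_allele && o_oa == e$effect_allele
    if (!direct && !swapped) {
      # retry on the complementary strand
      o_ea <- unname(COMPLEMENT[o_ea]); o_oa <- unname(COMPLEMENT[o_oa])
      direct <- o_ea == e$effect_allele && o_oa == e$other_allele
      swapped <- o_ea == e$other_allele && o_oa == e$effect_allele
    }
    if (direct) {
      keep_snp <- c(keep_snp, e$snp)
      bx <- c(bx, e$beta); sx <- c(sx, e$se)
      by <- c(by, o$beta); sy <- c(sy, o$se)
    } else if (swapped) {
      keep_snp <- c(keep_snp, e$snp)
      bx <- c(bx, e$beta); sx <- c(sx, e$se)
      by <- c(by, -o$beta); sy <- c(sy, o$se)
    } else {
      drop(e$snp, "allele mismatch")
    }
  }

  if (length(keep_snp) == 0) {
    stop("nothing to harmonize: no exposure instrument could be aligned ",
         "with the outcome records", call. = FALSE)
  }
  new_harmonized_set(
    keep_snp, bx, sx, by, sy,
    exposure = attr(exposure_instruments, "phenotype") %||% "exposure",
    outcome = attr(outcome_records, "phenotype") %||% "outcome",
    dropped = data.frame(snp = drop_snp, reason = drop_reason,
                         stringsAsFactors = FALSE)
  )
}

#' Flip a summary record to the opposite effect allele
#'
#' Re-expresses a [gwas_records] row set on the other allele: alleles are
#' swapped, betas negated and `eaf` replaced by `1 - eaf`. Applying the
#' transform twice returns the original table; it is the involution that
#' harmonization relies on.
#'
#' @param records a [gwas_records] table.
#' @param which logical or integer index of rows to flip (default all).
#' @return a [gwas_records] table.
#' @export
flip_effect_allele <- function(records, which = seq_len(nrow(records))) {
  stopifnot(inherits(records, "gwas_records"))
  out <- records
  ea <- out$effect_allele[which]
  out$effect_allele[which] <- out$other_allele[which]
  out$other_allele[which] <- ea
  out$beta[which] <- -out$beta[which]
  out$eaf[which] <- 1 - out$eaf[which]
  out
}

#' Write a harmonized set to delimited text
#'
#' Writes the per-SNP harmonized pairs to `path` as a TSV with columns
#' `snp`, `beta_exp`, `se_exp`, `beta_out`, `se_out`, and the dropped-SNP
#' table to a `*_dropped.tsv` sidecar. Numeric fields use full `%.17g`
#' precision so that [read_harmonized()] reproduces the set bit-for-bit.
#'
#' @param hset a [harmonized_set].
#' @param path output TSV path; the sidecar path is derived from it.
#' @return `path`, invisibly.
#' @export
write_harmonized <- function(hset, path) {
  stopifnot(inherits(hset, "harmonized_set"))
  fmt <- function(x) sprintf("%.17g", x)
  main <- data.frame(snp = hset$snp,
                     beta_exp = fmt(hset$beta_exp), se_exp = fmt(hset$se_exp),
                     beta_out = fmt(hset$beta_out), se_out = fmt(hset$se_out),
                     stringsAsFactors = FALSE)
  utils::write.table(main, path, sep = "\t", quote = FALSE, row.names = FALSE)
  sidecar <- sub("(\\.[A-Za-z]+)?$", "_dropped.tsv", path)
  utils::write.table(hset$dropped, sidecar, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a harmonized set written by [write_harmonized()]
#'
#' @param path TSV path previously passed to [write_harmonized()].
#' @param exposure,outcome labels for the restored set.
#' @return a [harmonized_set].
#' @export
read_harmonized <- function(path, exposure = "exposure", outcome = "outcome") {
  main <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE,
                            colClasses = c("character", rep("numeric", 4)))
  sidecar <- sub("(\\.[A-Za-z]+)?$", "_dropped.tsv", path)
  dropped <- if (file.exists(sidecar)) {
    utils::read.table(sidecar, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE,
                      colClasses = c("character", "character"))
  } else NULL
  new_harmonized_set(main$snp, main$beta_exp, main$se_exp,
                     main$beta_out, main$se_out,
                     exposure = exposure, outcome = outcome, dropped = dropped)
}
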