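#' Evaluate an expression under a local RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed`, then restores the
#' caller's RNG state so that library code never leaks random-state side
#' effects into user sessions.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite integer", call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Derive child seeds from a master seed
#'
#' Deterministically expands one seed into `n` sub-seeds (all < 2^31) so
#' that independent random streams (e.g. the two cohorts of a two-sample
#' design) can be driven from a single user-supplied seed.
#'
#' @keywords internal
#' @noRd
spawn_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Two-sided normal p-value from an estimate and its SE; SE of 0 maps to
# p = 0 for a nonzero estimate and p = 1 for an exactly null one.
z_pvalue <- function(beta, se) {
  if (se == 0) return(if (beta == 0) 1 else 0)
  2 * stats::pnorm(-abs(beta / se))
}
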