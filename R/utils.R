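# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so seeded subroutines do not
#' perturb the surrounding random stream.
#' @param seed integer seed, or NULL to leave the RNG stream untouched.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# DNA complement for strand flips
flip_strand <- function(alleles) chartr("ACGT", "TGCA", alleles)

is_palindromic_pair <- function(a1, a2) a2 == flip_strand(a1)

# Two-sided normal p-value for a z statistic
z_pval <- function(z) 2 * stats::pnorm(-abs(z))
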