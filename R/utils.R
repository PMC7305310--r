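#' @importFrom stats runif rbinom rbeta qbinom fisher.test p.adjust setNames
#' @importFrom utils head tail write.table read.delim
NULL

#' Evaluate an expression under a temporary RNG state
#'
#' Seeds the RNG, evaluates `expr`, and restores the caller's RNG state, so
#' seeded operations are reproducible without disturbing the session.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
withSeed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

#' Round half away from zero
#'
#' Fixed-point rounding with ties going up, matching how identification-rate
#' percentages are conventionally printed (e.g. 27.45 -> 27.5), unlike R's
#' round-half-to-even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal digits.
#' @return Rounded numeric vector.
#' @export
#' @examples
#' roundHalfUp(c(27.45098, 39.21569, 94.11765), 1)
roundHalfUp <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

isDecoyAccession <- function(accession) {
  startsWith(accession, DECOY_PREFIX)
}

stripDecoyPrefix <- function(accession) {
  sub(paste0("^", DECOY_PREFIX), "", accession)
}

## exact integer from fraction * n; errors if not representable
exactCount <- function(fraction, n, what) {
  k <- fraction * n
  if (abs(k - round(k)) > 1e-9) {
    stop(sprintf("%s * %d = %g is not an integer; exact allocation impossible",
                 what, n, k))
  }
  as.integer(round(k))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
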