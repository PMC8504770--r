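#' Evaluate an expression under a temporary RNG seed
#'
#' Runs \code{code} with the global RNG seeded at \code{seed} and restores
#' the caller's RNG state afterwards, so that no package function leaks
#' random-number state.  All randomness in the package flows through this
#' helper from one explicit seed.
#'
#' @param seed single integer seed.
#' @param code expression to evaluate.
#' @return The value of \code{code}.
#' @keywords internal
withSeed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Round half away from zero
#'
#' Base \code{round()} rounds half to even; report tables use conventional
#' half-up rounding so printed percentages match hand arithmetic.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return Rounded numeric vector.
#' @export
#' @examples
#' roundHalfUp(16.361, 2) # 16.36
#' roundHalfUp(0.125, 2)  # 0.13 (round() would give 0.12)
roundHalfUp <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# uniform random DNA of length n (call inside withSeed)
randomDna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# derive a stream-specific child seed from a master seed; kept below 2^31
childSeed <- function(seed, index) {
  (as.double(seed) * 1103L + as.double(index) * 12289L) %% 2147483629
}

`%||%` <- function(a, b) if (is.null(a)) b else a
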