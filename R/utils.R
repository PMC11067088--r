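#' Strip digit-grouping separators from a numeric string
#'
#' Physical positions in published chickpea tables are frequently typeset with
#' lakh/crore-style grouping (e.g. `"1,40,38,103"`). This removes every comma
#' (and surrounding whitespace) before numeric conversion, so both western and
#' Indian grouping parse identically.
#'
#' @param x character vector.
#' @return numeric vector; elements that do not parse become `NA` with a
#'   warning from [as.numeric()].
#' @examples
#' parse_grouped_number(c("1,40,38,103", "46,999", "12.5"))
#' @export
parse_grouped_number <- function(x) {
  as.numeric(gsub("[, ]", "", as.character(x)))
}

#' Derive a deterministic sub-stream seed
#'
#' All stochastic stages draw their seeds from one user seed through this
#' helper, so a single integer reproduces the full pipeline. Result is kept
#' strictly inside the 32-bit integer range.
#'
#' @param seed integer master seed.
#' @param stream integer or character stream label.
#' @return integer seed in `[1, 2^31 - 2]`.
#' @keywords internal
derive_seed <- function(seed, stream) {
  if (is.character(stream)) {
    raw <- as.integer(charToRaw(stream))
    stream <- sum(raw * seq_along(raw))
  }
  as.integer(1 + (abs(as.double(seed)) * 48271 + abs(as.double(stream)) * 16807) %%
               (2147483647 - 2))
}

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores `.Random.seed`, so seeded internals never perturb the
#' caller's RNG stream.
#'
#' @param seed integer seed, or `NULL` to leave the RNG alone.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# round-half-up at `digits`, used wherever printed tables round (base round()
# is round-half-even, which disagrees with published values like 2.10)
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a
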