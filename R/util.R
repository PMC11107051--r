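#' @useDynLib hcadan, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @keywords internal
"_PACKAGE"

# Evaluate an expression under a temporary RNG state; the caller's RNG
# stream is left untouched.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Seeds for sub-computations, drawn from the current RNG stream but kept
# within the 32-bit integer range.
draw_seed <- function(n = 1) sample.int(.Machine$integer.max - 1L, n)
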