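#' Derive a reproducible sub-seed from a master seed and a key path
#'
#' Every source of randomness in the package draws from its own stream, keyed
#' by the master seed plus a string path (e.g. `("rec", study_id)`), so that
#' subsetting or reordering one part of a simulation never perturbs the draws
#' of another.
#'
#' @param seed integer master seed.
#' @param ... character or numeric key components.
#' @return an integer in `[0, 2^31 - 2]`, usable with [set.seed()].
#' @export
derive_seed <- function(seed, ...) {
  key <- paste(c(format(seed, scientific = FALSE), ...), collapse = "/")
  # djb2-style string hash, kept inside the 32-bit signed range
  h <- 5381
  for (ch in utf8ToInt(key)) {
    h <- (h * 33 + ch) %% 2147483647
  }
  as.integer(h)
}

#' Evaluate an expression under a private RNG stream
#'
#' @param seed integer seed for the stream.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @keywords internal
with_stream <- function(seed, expr) {
  withr::with_seed(seed, expr)
}
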