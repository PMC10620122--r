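#' Derive a reproducible child seed from a root seed
#'
#' Every stochastic stage of the pipeline draws its own seed from the root
#' seed plus stage-specific integers, so stages are decoupled: changing the
#' number of permutations in one stage does not shift the random stream of
#' another. A multiplicative congruential step keeps the result inside the
#' 32-bit integer range R requires of `set.seed()`.
#'
#' @param seed integer root seed.
#' @param ... further integers identifying the stage (indices, sizes, ...).
#' @return a single integer in `[0, 2^31 - 2]`.
#' @keywords internal
derive_seed <- function(seed, ...) {
  ks <- c(...)
  s <- as.double(abs(as.integer(seed)) %% 2147483647)
  for (k in ks) {
    s <- (s * 48271 + (as.double(k) %% 2147483647) * 7919 + 1) %% 2147483647
  }
  as.integer(s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}
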