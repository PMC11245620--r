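#' Derive a reproducible child seed from a master seed
#'
#' Parameter sweeps need independent, reproducible random streams per
#' (parameter combination, covariance matrix, repetition). A single master
#' seed is mixed with the supplied integer indices through a fixed
#' integer-hash recurrence, yielding a deterministic child seed in
#' \code{[1, 2^31 - 2]} for each index tuple.
#'
#' @param master integer master seed.
#' @param ... integer indices identifying the stream (e.g. parameter
#'   combination index, matrix index, repetition index).
#' @return A single integer seed suitable for [set.seed()].
#' @examples
#' child_seed(1, 2, 3)
#' @export
child_seed <- function(master, ...) {
  idx <- c(...)
  stopifnot(length(master) == 1L, is.finite(master))
  # multiplicative hash mod a prime below 2^31; arithmetic kept in doubles
  # (exact for intermediate values < 2^53)
  m <- 2147483587
  h <- (as.numeric(master) %% m)
  for (i in idx) {
    h <- (h * 48271 + as.numeric(i) + 1) %% m
  }
  as.integer(h %% (m - 1L) + 1)
}

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}
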