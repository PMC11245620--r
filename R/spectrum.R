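#' Power-law principal component variance spectrum
#'
#' Models the within-set variance structure of a dataset in its principal
#' component coordinate system as a power law: the variance of component
#' \eqn{i} is \eqn{c \, i^{a}} with decay exponent \eqn{a \le 0}. A flat
#' spectrum (\code{a = 0}) corresponds to white (isotropic) data; more
#' negative exponents concentrate variance in the leading components, as
#' observed in imaging and behavioral datasets.
#'
#' @param p number of features (positive integer).
#' @param a decay exponent, must be \code{<= 0}.
#' @param c scale factor (positive); only rescales all results, default 1.
#' @return Numeric vector of length \code{p} with strictly positive,
#'   non-increasing variances.
#' @examples
#' powerlaw_spectrum(4, 0)        # flat: 1 1 1 1
#' powerlaw_spectrum(3, -1)       # 1, 1/2, 1/3
#' @export
powerlaw_spectrum <- function(p, a, c = 1) {
  if (length(p) != 1L || p < 1 || p != round(p)) {
    stop("'p' must be a positive integer")
  }
  if (length(a) != 1L || !is.finite(a) || a > 0) {
    stop("'a' must be a finite decay exponent <= 0")
  }
  if (length(c) != 1L || !is.finite(c) || c <= 0) {
    stop("'c' must be positive")
  }
  c * seq_len(p)^a
}

#' Explained-variance admissibility of a candidate weight vector
#'
#' A planted association mode should explain a non-negligible share of
#' within-set variance, otherwise its scores would be dominated by noise.
#' A unit weight vector \eqn{w} is admissible when the variance of its score,
#' \eqn{w^\top \Sigma w} with \eqn{\Sigma = \mathrm{diag}(\sigma)}, exceeds
#' half the average variance of a principal component,
#' \eqn{\mathrm{tr}(\Sigma) / (2p)}.
#'
#' @param w unit-norm weight vector.
#' @param sigma within-set variance spectrum (same length as \code{w}).
#' @return \code{TRUE} if the weight is admissible.
#' @export
admissible_weight <- function(w, sigma) {
  if (length(w) != length(sigma)) {
    stop("'w' and 'sigma' must have the same length")
  }
  sum(w^2 * sigma) > 0.5 * sum(sigma) / length(sigma)
}

#' Normalize a weight vector to unit score variance
#'
#' CCA weight vectors are constrained to give scores with unit variance
#' under the population covariance: \eqn{w^\top \Sigma w = 1} with
#' \eqn{\Sigma = \mathrm{diag}(\sigma)}. Any nonzero vector can be rescaled
#' to satisfy this.
#'
#' @param w_raw nonzero weight vector.
#' @param sigma within-set variance spectrum.
#' @return Rescaled weight vector with unit score variance.
#' @export
normalize_cca_weight <- function(w_raw, sigma) {
  if (length(w_raw) != length(sigma)) {
    stop("'w_raw' and 'sigma' must have the same length")
  }
  q <- sum(w_raw^2 * sigma)
  if (q <= 0) stop("'w_raw' must be a nonzero vector")
  w_raw / sqrt(q)
}
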