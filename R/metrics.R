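#' Cosine similarity between two vectors
#'
#' @param a,b numeric vectors of equal length, both nonzero.
#' @return Signed cosine similarity in \code{[-1, 1]}.
#' @export
cosine_similarity <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cosine similarity of a zero vector is undefined")
  sum(a * b) / (na * nb)
}

#' Relative error of the estimated association strength
#'
#' \eqn{\Delta r = (\hat r - r_{true}) / r_{true}}. Positive values indicate
#' overestimation, the typical in-sample behavior at small sample sizes.
#'
#' @param r_hat estimated association strength.
#' @param r_true true (population) association strength, must be \code{> 0}.
#' @return Signed relative error.
#' @export
relative_assoc_error <- function(r_hat, r_true) {
  if (any(r_true <= 0)) stop("'r_true' must be > 0 for a relative error")
  (r_hat - r_true) / r_true
}

#' Weight estimation error
#'
#' One minus the absolute cosine similarity between estimated and true
#' weights, computed separately for the X and Y sets; the greater of the
#' two errors is reported. The absolute value absorbs the inherent sign
#' ambiguity of singular vectors. Bounded in \code{[0, 1]}.
#'
#' @param wx_hat,wy_hat estimated weight vectors.
#' @param wx_true,wy_true true weight vectors.
#' @return Weight error in \code{[0, 1]}.
#' @export
weight_error <- function(wx_hat, wy_hat, wx_true, wy_true) {
  max(1 - abs(cosine_similarity(wx_hat, wx_true)),
      1 - abs(cosine_similarity(wy_hat, wy_true)))
}

#' Score estimation error on a common test set
#'
#' Scores index individual observations, so estimated and true scores are
#' only comparable when computed on the same observations. Both weight sets
#' are therefore applied to a common test-set pair, and the error is the
#' maximum over sets of one minus the absolute Pearson correlation between
#' the two resulting score vectors. Bounded in \code{[0, 1]} and invariant
#' to rescaling of either weight vector.
#'
#' @param wx_hat,wy_hat estimated weight vectors.
#' @param truth a true solution as returned by [true_solution()] (or any
#'   list with \code{w_x}, \code{w_y}).
#' @param test_pair a \code{dataset_pair} used as the common test set.
#' @return Score error in \code{[0, 1]}.
#' @export
score_error <- function(wx_hat, wy_hat, truth, test_pair) {
  tx_hat <- drop(test_pair$X %*% wx_hat)
  ty_hat <- drop(test_pair$Y %*% wy_hat)
  tx <- drop(test_pair$X %*% truth$w_x)
  ty <- drop(test_pair$Y %*% truth$w_y)
  if (stats::sd(tx_hat) == 0 || stats::sd(ty_hat) == 0 ||
      stats::sd(tx) == 0 || stats::sd(ty) == 0) {
    stop("degenerate (constant) scores on the test set")
  }
  max(1 - abs(stats::cor(tx_hat, tx)), 1 - abs(stats::cor(ty_hat, ty)))
}

#' Loading estimation error
#'
#' One minus the absolute Pearson correlation, across variables, between
#' estimated and true loading vectors, maximized over the two sets. Both
#' loading vectors should be computed on a common test set: estimated
#' loadings correlate the test columns with scores under estimated weights,
#' true loadings with scores under the true weights. With only two
#' variables per set the correlation across variables is degenerate
#' (always \eqn{\pm 1}); a warning is issued for \code{p < 3}.
#'
#' @param loadings_x_hat,loadings_y_hat estimated loading vectors.
#' @param loadings_x_true,loadings_y_true true loading vectors.
#' @return Loading error in \code{[0, 1]}.
#' @export
loading_error <- function(loadings_x_hat, loadings_y_hat,
                          loadings_x_true, loadings_y_true) {
  if (length(loadings_x_hat) < 3 || length(loadings_y_hat) < 3) {
    warning("loading error is degenerate for sets with fewer than 3 variables")
  }
  max(1 - abs(stats::cor(loadings_x_hat, loadings_x_true)),
      1 - abs(stats::cor(loadings_y_hat, loadings_y_true)))
}

#' Loadings of test data under a given weight vector
#'
#' Correlates each column of a test matrix with the score obtained by
#' projecting the test data onto \code{w}; the ingredient of the loading
#' error metric.
#'
#' @param data_test test data matrix.
#' @param w weight vector.
#' @return Vector of per-variable loadings.
#' @export
test_loadings <- function(data_test, w) {
  drop(stats::cor(data_test, drop(data_test %*% w)))
}

#' Stability of estimated vectors across independent datasets
#'
#' The mean absolute cosine similarity over all unordered pairs of weight
#' (or loading) vectors estimated from independently drawn datasets of the
#' same population. 1 means identical axes (up to sign), 0 orthogonality.
#'
#' @param v_list list of two or more numeric vectors of equal length.
#' @return Stability value in \code{[0, 1]}.
#' @export
stability <- function(v_list) {
  if (length(v_list) < 2) stop("need at least 2 vectors")
  pairs <- utils::combn(length(v_list), 2)
  mean(apply(pairs, 2, function(ij) {
    abs(cosine_similarity(v_list[[ij[1]]], v_list[[ij[2]]]))
  }))
}

#' Similarity of a vector to the first principal component axis
#'
#' Signed cosine similarity between a weight or loading vector and the
#' first principal component axis of its dataset. In the generating
#' convention of the synthetic models, PC1 is the first coordinate axis.
#' High values diagnose the bias of PLS weights toward dominant variance
#' directions.
#'
#' @param v numeric vector.
#' @return Signed similarity in \code{[-1, 1]}.
#' @export
pc1_similarity <- function(v) {
  e1 <- c(1, rep(0, length(v) - 1))
  cosine_similarity(v, e1)
}

#' Reference distribution of the cosine similarity of random vectors
#'
#' The cosine similarity between a uniformly random unit vector in
#' \code{n_dim} dimensions and any fixed unit vector is distributed as
#' \eqn{2\tilde X - 1} with
#' \eqn{\tilde X \sim \mathrm{Beta}((n-1)/2, (n-1)/2)}; equivalently its
#' density on \code{[-1, 1]} is
#' \eqn{f(x) = (1 - x^2)^{(n-3)/2} / B((n-1)/2, 1/2)}. For \code{n_dim = 3}
#' the density is uniform at 1/2; the variance is \code{1/n_dim} for all
#' dimensions. Used as the chance baseline when interpreting PC1
#' similarities.
#'
#' @param n_dim dimension (\code{>= 2}).
#' @return A list of class \code{cosine_reference} with functions
#'   \code{density(x)}, \code{cdf(x)}, \code{quantile(p)},
#'   \code{sample(n, seed)}, and moments \code{mean} (0) and
#'   \code{variance} (\code{1/n_dim}).
#' @export
random_cosine_reference <- function(n_dim) {
  if (length(n_dim) != 1L || n_dim < 2 || n_dim != round(n_dim)) {
    stop("'n_dim' must be an integer >= 2")
  }
  k <- (n_dim - 1) / 2
  structure(
    list(
      n_dim = as.integer(n_dim),
      density = function(x) {
        ifelse(abs(x) <= 1, stats::dbeta((x + 1) / 2, k, k) / 2, 0)
      },
      cdf = function(x) stats::pbeta((x + 1) / 2, k, k),
      quantile = function(p) 2 * stats::qbeta(p, k, k) - 1,
      sample = function(n, seed = 1L) {
        with_seed(seed, 2 * stats::rbeta(n, k, k) - 1)
      },
      mean = 0,
      variance = 1 / n_dim
    ),
    class = "cosine_reference"
  )
}

#' Statistical power at a significance threshold
#'
#' The fraction of p-values strictly below \code{alpha}; with the add-one
#' permutation p-value convention an attainable p never equals zero, so a
#' strict inequality is well defined.
#'
#' @param p_values vector of p-values in \code{(0, 1]}.
#' @param alpha significance threshold (default 0.05).
#' @return Power in \code{[0, 1]}.
#' @export
power_fraction <- function(p_values, alpha = 0.05) {
  if (length(p_values) == 0) stop("empty p-value vector")
  mean(p_values < alpha)
}
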