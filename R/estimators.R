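#' Fit CCA or PLS from covariance blocks
#'
#' Computes the first association mode directly from covariance matrices.
#' For PLS the weights are the leading singular vectors of the raw
#' cross-covariance block and the association strength is its leading
#' singular value (the score covariance). For CCA the leading singular
#' triplet of the whitened cross-covariance
#' \eqn{\Sigma_{XX}^{-1/2}\Sigma_{XY}\Sigma_{YY}^{-1/2}} gives the first
#' canonical correlation, and the weights are recovered as
#' \eqn{w = \Sigma^{-1/2} u}. Whitening uses the symmetric inverse square
#' root from an eigendecomposition of the within-set blocks; no
#' regularization is applied, so those blocks must be positive definite.
#'
#' Sign convention: each weight vector is flipped so that its
#' largest-magnitude entry is positive. All downstream error metrics use
#' absolute cosine similarities or correlations, so this affects reporting
#' only.
#'
#' @param sigma_xx,sigma_yy within-set covariance matrices (or variance
#'   vectors, interpreted as diagonal matrices).
#' @param sigma_xy between-set covariance matrix.
#' @param method \code{"cca"} or \code{"pls"}.
#' @return A list of class \code{cca_pls_fit} with \code{w_x_hat},
#'   \code{w_y_hat}, \code{assoc_strength} and \code{method}.
#' @export
fit_from_covariance <- function(sigma_xx, sigma_yy, sigma_xy,
                                method = c("cca", "pls")) {
  method <- match.arg(method)
  sxx <- as_cov_matrix(sigma_xx)
  syy <- as_cov_matrix(sigma_yy)
  if (nrow(sigma_xy) != nrow(sxx) || ncol(sigma_xy) != nrow(syy)) {
    stop("dimensions of 'sigma_xy' are inconsistent with the within-set blocks")
  }
  if (method == "pls") {
    sv <- svd(sigma_xy, nu = 1, nv = 1)
    w_x <- sv$u[, 1]
    w_y <- sv$v[, 1]
    assoc <- sv$d[1]
  } else {
    wxi <- inv_sqrt_sym(sxx)
    wyi <- inv_sqrt_sym(syy)
    k <- wxi %*% sigma_xy %*% wyi
    sv <- svd(k, nu = 1, nv = 1)
    w_x <- drop(wxi %*% sv$u[, 1])
    w_y <- drop(wyi %*% sv$v[, 1])
    assoc <- min(sv$d[1], 1)
  }
  sgn <- function(w) if (w[which.max(abs(w))] < 0) -w else w
  structure(
    list(w_x_hat = sgn(w_x), w_y_hat = sgn(w_y),
         assoc_strength = assoc, method = method),
    class = "cca_pls_fit"
  )
}

as_cov_matrix <- function(s) {
  if (is.matrix(s)) s else diag(s, length(s))
}

# Symmetric inverse square root via eigendecomposition; errors on a
# numerically singular matrix (CCA needs invertible within-set covariance).
inv_sqrt_sym <- function(s) {
  e <- eigen(s, symmetric = TRUE)
  if (min(e$values) <= 1e-12 * max(e$values)) {
    stop("within-set covariance matrix is singular or nearly singular")
  }
  e$vectors %*% (t(e$vectors) / sqrt(e$values))
}

#' Fit CCA or PLS to a pair of data matrices
#'
#' Column-centers both matrices, forms the sample covariance blocks with
#' denominator \code{n - 1}, delegates the mode extraction to
#' [fit_from_covariance()], and augments the result with per-observation
#' scores (data times weights) and loadings (Pearson correlation of each
#' column with the set's score).
#'
#' @param X,Y numeric matrices with equal row counts.
#' @param method \code{"cca"} or \code{"pls"}.
#' @return A \code{cca_pls_fit} with weights, \code{assoc_strength},
#'   \code{scores_x}, \code{scores_y}, \code{loadings_x}, \code{loadings_y}.
#' @examples
#' m <- generate_model(4, 4, -1, -1, 0.5, "cca", seed = 2)
#' d <- sample_dataset(m, 500, seed = 3)
#' fit_cca_pls(d$X, d$Y, "cca")$assoc_strength
#' @export
fit_cca_pls <- function(X, Y, method = c("cca", "pls")) {
  method <- match.arg(method)
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("'X' and 'Y' must have equal row counts")
  n <- nrow(X)
  if (method == "cca" && n - 1 <= max(ncol(X), ncol(Y))) {
    stop("CCA needs n - 1 > max(p_x, p_y) for invertible sample covariances")
  }
  xc <- scale(X, center = TRUE, scale = FALSE)
  yc <- scale(Y, center = TRUE, scale = FALSE)
  fit <- fit_from_covariance(crossprod(xc) / (n - 1),
                             crossprod(yc) / (n - 1),
                             crossprod(xc, yc) / (n - 1),
                             method = method)
  fit$scores_x <- drop(xc %*% fit$w_x_hat)
  fit$scores_y <- drop(yc %*% fit$w_y_hat)
  fit$loadings_x <- drop(stats::cor(xc, fit$scores_x))
  fit$loadings_y <- drop(stats::cor(yc, fit$scores_y))
  fit$n <- n
  fit
}

#' @export
print.cca_pls_fit <- function(x, ...) {
  cat(sprintf("%s fit: association strength %.4f (p_x = %d, p_y = %d)\n",
              toupper(x$method), x$assoc_strength,
              length(x$w_x_hat), length(x$w_y_hat)))
  invisible(x)
}

#' Project test data onto fitted weights
#'
#' Applies previously estimated weight vectors to held-out data without any
#' refitting, returning the test scores used by the score and loading error
#' metrics and by cross-validation.
#'
#' @param fit a \code{cca_pls_fit} (or any list with \code{w_x_hat},
#'   \code{w_y_hat}).
#' @param X_test,Y_test test data matrices with matching feature counts.
#' @param center center the test columns before projecting (default TRUE).
#' @return List with score vectors \code{scores_x} and \code{scores_y}.
#' @export
score_test_data <- function(fit, X_test, Y_test, center = TRUE) {
  X_test <- as.matrix(X_test); Y_test <- as.matrix(Y_test)
  if (ncol(X_test) != length(fit$w_x_hat) ||
      ncol(Y_test) != length(fit$w_y_hat)) {
    stop("test data feature dimensions do not match the fitted weights")
  }
  if (center) {
    X_test <- scale(X_test, center = TRUE, scale = FALSE)
    Y_test <- scale(Y_test, center = TRUE, scale = FALSE)
  }
  list(scores_x = drop(X_test %*% fit$w_x_hat),
       scores_y = drop(Y_test %*% fit$w_y_hat))
}

#' Cross-validated association strength
#'
#' Splits the observations into \code{k} random near-equal folds, fits
#' CCA/PLS on each training portion, projects the held-out fold with the
#' estimated weights, and records the correlation (CCA) or covariance (PLS)
#' of the resulting test scores. Because singular-vector signs are
#' arbitrary, each fold value is orientation-aligned: it is multiplied by
#' the sign of the training-score association under the same weights, so a
#' genuinely positive association yields positive fold values and null data
#' scatter around zero.
#'
#' @inheritParams fit_cca_pls
#' @param k_folds number of folds (default 5).
#' @param seed integer seed controlling the fold assignment.
#' @return List of class \code{cross_val_result} with \code{fold_values}
#'   and their \code{mean_value}.
#' @export
cross_validate <- function(X, Y, method = c("cca", "pls"), k_folds = 5L,
                           seed = 1L) {
  method <- match.arg(method)
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  if (nrow(Y) != n) stop("'X' and 'Y' must have equal row counts")
  folds <- with_seed(seed, sample(rep_len(seq_len(k_folds), n)))
  vals <- vapply(seq_len(k_folds), function(k) {
    tr <- folds != k
    fit <- fit_cca_pls(X[tr, , drop = FALSE], Y[tr, , drop = FALSE], method)
    sc <- score_test_data(fit, X[!tr, , drop = FALSE], Y[!tr, , drop = FALSE])
    orientation <- sign(stats::cov(fit$scores_x, fit$scores_y))
    if (orientation == 0) orientation <- 1
    orientation * if (method == "cca") {
      stats::cor(sc$scores_x, sc$scores_y)
    } else {
      stats::cov(sc$scores_x, sc$scores_y)
    }
  }, numeric(1))
  structure(list(fold_values = vals, mean_value = mean(vals)),
            class = "cross_val_result")
}

#' Permutation test for the between-set association strength
#'
#' Builds the null distribution of the association strength by refitting
#' after random row permutations of \code{Y} (with \code{X} fixed), which
#' breaks any between-set association while preserving both within-set
#' structures. The one-sided p-value uses the add-one convention
#' \eqn{p = (1 + \#\{null \ge observed\}) / (n_{perm} + 1)}, so attainable
#' p-values are strictly positive.
#'
#' Row permutations leave the within-set sample covariances unchanged, so
#' the whitening transforms are computed once and only the cross-covariance
#' is recomputed per permutation; the null values are identical to refitting
#' from scratch on the permuted data.
#'
#' @inheritParams fit_cca_pls
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed for the permutation stream.
#' @return List of class \code{permutation_result} with \code{observed},
#'   \code{null_values} and \code{p_value}.
#' @export
permutation_test <- function(X, Y, method = c("cca", "pls"), n_perm = 1000L,
                             seed = 1L) {
  method <- match.arg(method)
  if (n_perm < 1) stop("'n_perm' must be >= 1")
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  if (nrow(Y) != n) stop("'X' and 'Y' must have equal row counts")
  if (n < 3) stop("need at least 3 observations")

  xc <- scale(X, center = TRUE, scale = FALSE)
  yc <- scale(Y, center = TRUE, scale = FALSE)
  observed <- fit_cca_pls(X, Y, method)$assoc_strength

  if (method == "cca") {
    xw <- xc %*% inv_sqrt_sym(crossprod(xc) / (n - 1))
    yw <- yc %*% inv_sqrt_sym(crossprod(yc) / (n - 1))
  } else {
    xw <- xc
    yw <- yc
  }
  null_values <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      perm <- sample.int(n)
      k <- crossprod(xw, yw[perm, , drop = FALSE]) / (n - 1)
      v <- svd(k, nu = 0, nv = 0)$d[1]
      if (method == "cca") min(v, 1) else v
    }, numeric(1))
  })
  p <- (1 + sum(null_values >= observed)) / (n_perm + 1)
  structure(list(observed = observed, null_values = null_values, p_value = p),
            class = "permutation_result")
}
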