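#' Remove confound contributions by linear regression
#'
#' Subtracts the least-squares linear prediction of each data column from
#' the confound matrix: \eqn{X_{dec} = X - C\beta} with
#' \eqn{\beta = (C^\top C)^{-1} C^\top X}. The residuals are orthogonal to
#' every confound column. Rank-deficient confound matrices are handled via
#' the pseudo-solution of the normal equations (with a warning).
#'
#' @param data numeric matrix (observations by variables), no missing values.
#' @param confounds numeric matrix of confounds with the same row count.
#' @return Deconfounded data matrix.
#' @export
deconfound <- function(data, confounds) {
  data <- as.matrix(data); confounds <- as.matrix(confounds)
  if (nrow(data) != nrow(confounds)) {
    stop("'data' and 'confounds' must have equal row counts")
  }
  if (anyNA(confounds)) stop("'confounds' must not contain missing values")
  if (anyNA(data)) stop("'data' must not contain missing values")
  qc <- qr(confounds)
  if (qc$rank < ncol(confounds)) {
    warning("confound matrix is rank deficient; using the least-squares pseudo-solution")
  }
  beta <- qr.coef(qc, data)
  beta[is.na(beta)] <- 0
  data - confounds %*% beta
}

#' Rank-based inverse normal transformation
#'
#' Replaces the non-missing values of a column by normal quantiles of their
#' Blom-adjusted ranks, \eqn{\Phi^{-1}((rank - 3/8)/(m + 1/4))} with
#' \eqn{m} the number of non-missing values and average ranks for ties,
#' then centers the result to mean 0. Missing entries are preserved (for
#' confound columns they are conventionally set to 0 afterwards, the
#' post-transform mean).
#'
#' @param x numeric vector, possibly with missing values; at least 3
#'   distinct non-missing values required.
#' @return Transformed vector with missing entries preserved.
#' @export
inverse_normal_transform <- function(x) {
  obs <- !is.na(x)
  v <- x[obs]
  if (length(v) < 3) stop("need at least 3 non-missing values")
  if (length(unique(v)) == 1) stop("cannot transform an all-constant column")
  r <- rank(v, ties.method = "average")
  q <- stats::qnorm((r - 3 / 8) / (length(v) + 1 / 4))
  x[obs] <- q - mean(q)
  x
}

#' PCA reduction to leading component scores
#'
#' Column-centers the data, takes its singular value decomposition, and
#' returns the first \code{k} left singular vectors scaled by their
#' singular values, so the variance of component \eqn{j} equals its
#' eigenvalue. The right singular vectors and singular values are attached
#' as attributes \code{"rotation"} and \code{"d"} for reconstruction.
#'
#' @param data numeric matrix (observations by variables), no missing values.
#' @param k number of components to retain (\code{<= min(n, p)}).
#' @return \code{n} by \code{k} matrix of principal component scores.
#' @export
pca_reduce <- function(data, k) {
  data <- as.matrix(data)
  if (anyNA(data)) stop("'data' must not contain missing values")
  if (k > min(dim(data))) stop("'k' exceeds min(n, p)")
  xc <- scale(data, center = TRUE, scale = FALSE)
  sv <- svd(xc, nu = k, nv = k)
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k)
  attr(scores, "rotation") <- sv$v
  attr(scores, "d") <- sv$d[seq_len(k)]
  scores
}

#' Nearest positive definite matrix
#'
#' Projects a symmetric matrix onto the positive definite cone by Higham's
#' alternating-projections algorithm (via [Matrix::nearPD()]), returning a
#' symmetric matrix with strictly positive eigenvalues that is close to the
#' input in Frobenius norm. A matrix that is already positive definite is
#' returned unchanged up to numerical tolerance. Needed to repair
#' indefinite covariance estimates such as pairwise-complete covariances of
#' data with missing entries.
#'
#' @param m square symmetric numeric matrix.
#' @return Positive definite symmetric matrix of the same dimension.
#' @export
nearest_positive_definite <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("'m' must be square")
  if (max(abs(m - t(m))) > 1e-8 * max(1, max(abs(m)))) {
    stop("'m' must be symmetric")
  }
  ev <- eigen((m + t(m)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) > 1e-12 * max(abs(ev))) return((m + t(m)) / 2)
  out <- Matrix::nearPD(m, ensureSymmetry = TRUE, base.matrix = TRUE)
  out$mat
}

#' Pairwise-complete covariance between observations
#'
#' Computes an observation-by-observation covariance matrix across
#' variables, where each entry uses only the variables observed for both
#' members of the pair. This avoids imputation for missing-at-random data
#' but can yield an indefinite matrix, which should be repaired with
#' [nearest_positive_definite()] before eigendecomposition.
#'
#' @param data numeric matrix (observations by variables) with missing
#'   entries allowed; every pair of observations must share at least 2
#'   observed variables.
#' @return Symmetric observation-by-observation covariance matrix.
#' @export
pairwise_complete_covariance <- function(data) {
  data <- as.matrix(data)
  out <- stats::cov(t(data), use = "pairwise.complete.obs")
  if (anyNA(out)) {
    stop("some pairs of observations share fewer than 2 observed variables")
  }
  out
}

#' Decay exponent of a variance spectrum
#'
#' Estimates the power-law decay constant of a principal component variance
#' spectrum as the slope of a linear regression (with intercept) of
#' log(variance) on log(component index), using as many leading components
#' as needed to explain the requested fraction of total variance (at least
#' 3).
#'
#' @param variances non-increasing vector of component variances.
#' @param coverage fraction of variance the retained components must
#'   explain (e.g. 0.3 or 0.9).
#' @return Estimated decay exponent (slope).
#' @export
spectrum_decay <- function(variances, coverage = 0.9) {
  if (coverage <= 0 || coverage > 1) stop("'coverage' must be in (0, 1]")
  cum <- cumsum(variances) / sum(variances)
  k <- which(cum >= coverage)[1]
  k <- max(k, 3L)
  if (length(variances) < 3) stop("need at least 3 components")
  k <- min(k, length(variances))
  if (k < 3) stop("fewer than 3 components retained at this coverage")
  idx <- seq_len(k)
  unname(stats::coef(stats::lm(log(variances[idx]) ~ log(idx)))[2])
}

#' Subsampled non-overlapping stability analysis
#'
#' Audits the sample-size dependence of a CCA/PLS analysis on a given
#' dataset. For each of \code{n_sizes} logarithmically spaced subsample
#' sizes (up to half the observations), repeatedly draws two disjoint
#' subsamples, fits the model on each, and records the in-sample
#' association strength, the 5-fold cross-validated association, a
#' permutation-null association summary and p-value, the cross-half weight
#' stability (mean absolute cosine similarity over the two sets), and the
#' PC1 similarity of the first-half weights.
#'
#' @param X,Y data matrices with equal row counts.
#' @param method \code{"cca"} or \code{"pls"}.
#' @param n_sizes number of subsample sizes (default 5).
#' @param n_reps disjoint subsample pairs per size (default 100).
#' @param n_perm permutations per repetition for the null (default 100).
#' @param min_size smallest subsample size; defaults to
#'   \code{max(p_x, p_y) + 2} (CCA rank requirement) or 20, whichever is
#'   larger.
#' @param k_folds folds for cross-validation (default 5).
#' @param seed master seed.
#' @return Object of class \code{stability_curve}: a list with
#'   \code{records} (one row per size and repetition: \code{size},
#'   \code{rep_index}, \code{assoc_in}, \code{assoc_cv}, \code{null_mean},
#'   \code{p_value}, \code{weight_stability}, \code{pc1_sim}) and
#'   \code{curve} (per-size means).
#' @export
subsampled_stability_analysis <- function(X, Y, method = c("cca", "pls"),
                                          n_sizes = 5L, n_reps = 100L,
                                          n_perm = 100L, min_size = NULL,
                                          k_folds = 5L, seed = 1L) {
  method <- match.arg(method)
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  if (nrow(Y) != n) stop("'X' and 'Y' must have equal row counts")
  if (is.null(min_size)) {
    min_size <- max(20L, max(ncol(X), ncol(Y)) + 2L, 2L * k_folds)
  }
  max_size <- floor(n / 2)
  if (min_size > max_size) {
    stop("not enough observations for two disjoint subsamples of the minimum size")
  }
  sizes <- unique(round(exp(seq(log(min_size), log(max_size),
                                length.out = n_sizes))))
  recs <- list()
  for (si in seq_along(sizes)) {
    s <- sizes[si]
    for (rep in seq_len(n_reps)) {
      idx <- with_seed(child_seed(seed, si, rep, 0), sample.int(n, 2 * s))
      a <- idx[seq_len(s)]
      b <- idx[s + seq_len(s)]
      fit_a <- fit_cca_pls(X[a, , drop = FALSE], Y[a, , drop = FALSE], method)
      fit_b <- fit_cca_pls(X[b, , drop = FALSE], Y[b, , drop = FALSE], method)
      cv <- cross_validate(X[a, , drop = FALSE], Y[a, , drop = FALSE],
                           method, k_folds = k_folds,
                           seed = child_seed(seed, si, rep, 1))
      pt <- permutation_test(X[a, , drop = FALSE], Y[a, , drop = FALSE],
                             method, n_perm = n_perm,
                             seed = child_seed(seed, si, rep, 2))
      recs[[length(recs) + 1L]] <- data.frame(
        size = s, rep_index = rep,
        assoc_in = mean(c(fit_a$assoc_strength, fit_b$assoc_strength)),
        assoc_cv = cv$mean_value,
        null_mean = mean(pt$null_values),
        p_value = pt$p_value,
        weight_stability = mean(c(
          abs(cosine_similarity(fit_a$w_x_hat, fit_b$w_x_hat)),
          abs(cosine_similarity(fit_a$w_y_hat, fit_b$w_y_hat)))),
        pc1_sim = pc1_similarity(fit_a$w_x_hat)
      )
    }
  }
  records <- do.call(rbind, recs)
  curve <- do.call(rbind, lapply(split(records, records$size), function(d) {
    data.frame(size = d$size[1], assoc_in = mean(d$assoc_in),
               assoc_cv = mean(d$assoc_cv), null_mean = mean(d$null_mean),
               weight_stability = mean(d$weight_stability),
               pc1_sim = mean(d$pc1_sim))
  }))
  curve <- curve[order(curve$size), ]
  rownames(curve) <- NULL
  structure(list(records = records, curve = curve, method = method,
                 sizes = sizes),
            class = "stability_curve")
}

#' Synthetic empirical-style fixture with confounds and missingness
#'
#' Generates paired data emulating the structure of empirical
#' imaging/behavior datasets: a draw from a generative covariance model
#' with linear confound contributions added to both sets, and
#' missing-at-random entries injected into \code{Y} only (behavior-style
#' data). The ground truth (model, confound coefficients, missingness
#' mask) is returned for recovery tests.
#'
#' @param model a \code{cov_model}.
#' @param n number of observations.
#' @param q_confounds number of confound variables.
#' @param missing_rate fraction of \code{Y} entries set missing, in
#'   \code{[0, 0.5]}.
#' @param seed integer seed.
#' @param confound_strength scale of the confound coefficients relative to
#'   unit-variance confounds (default 0.5; 0 disables confound effects).
#' @return A list with \code{x} and \code{y} (each a list with \code{data}
#'   and \code{confounds}) and \code{truth} (the model, coefficient
#'   matrices \code{beta_x}, \code{beta_y}, and the \code{missing_mask}).
#' @export
generate_empirical_fixture <- function(model, n, q_confounds = 3L,
                                       missing_rate = 0, seed = 1L,
                                       confound_strength = 0.5) {
  stopifnot(inherits(model, "cov_model"))
  if (missing_rate < 0 || missing_rate > 0.5) {
    stop("'missing_rate' must be in [0, 0.5]")
  }
  d <- sample_dataset(model, n, seed = child_seed(seed, 1))
  px <- ncol(d$X); py <- ncol(d$Y)
  parts <- with_seed(child_seed(seed, 2), {
    list(
      confounds = matrix(stats::rnorm(n * q_confounds), n, q_confounds),
      beta_x = confound_strength *
        matrix(stats::rnorm(q_confounds * px), q_confounds, px),
      beta_y = confound_strength *
        matrix(stats::rnorm(q_confounds * py), q_confounds, py),
      mask = matrix(stats::runif(n * py) < missing_rate, n, py)
    )
  })
  x_data <- d$X + parts$confounds %*% parts$beta_x
  y_data <- d$Y + parts$confounds %*% parts$beta_y
  y_data[parts$mask] <- NA_real_
  list(
    x = list(data = x_data, confounds = parts$confounds),
    y = list(data = y_data, confounds = parts$confounds),
    truth = list(model = model, beta_x = parts$beta_x,
                 beta_y = parts$beta_y, missing_mask = parts$mask)
  )
}
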