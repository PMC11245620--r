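#' Between-set cross-covariance for a planted PLS mode
#'
#' For PLS the weight vectors are the singular vectors of the raw
#' cross-covariance block, so a rank-1 association with unit weight vectors
#' \eqn{w_X, w_Y} and singular value \eqn{s} is planted as
#' \eqn{\Sigma_{XY} = s\, w_X w_Y^\top}. The singular value is re-expressed
#' through the true between-set correlation:
#' \deqn{s = r_{true} \sqrt{(w_X^\top \Sigma_{XX} w_X)(w_Y^\top \Sigma_{YY} w_Y)}}
#'
#' @param w_x,w_y unit-norm weight vectors.
#' @param r_true true between-set correlation in \code{[0, 1)}.
#' @param sigma_xx,sigma_yy within-set variance spectra.
#' @return The \code{p_x} by \code{p_y} cross-covariance matrix.
#' @export
build_pls_cross_cov <- function(w_x, w_y, r_true, sigma_xx, sigma_yy) {
  check_r_true(r_true)
  if (abs(sum(w_x^2) - 1) > 1e-8 || abs(sum(w_y^2) - 1) > 1e-8) {
    stop("PLS weights must be unit-norm")
  }
  s <- r_true * sqrt(sum(w_x^2 * sigma_xx) * sum(w_y^2 * sigma_yy))
  s * tcrossprod(w_x, w_y)
}

#' Between-set cross-covariance for a planted CCA mode
#'
#' For CCA the singular value decomposition applies to the whitened
#' cross-covariance \eqn{\Sigma_{XX}^{-1/2}\Sigma_{XY}\Sigma_{YY}^{-1/2}},
#' whose singular values are the canonical correlations and whose singular
#' vectors map to the weights via \eqn{w = \Sigma^{-1/2} u}. Inverting that
#' relation for a single mode with weights normalized to unit score
#' variance (\eqn{w^\top \Sigma w = 1}) gives
#' \deqn{\Sigma_{XY} = \Sigma_{XX}^{1/2} (\Sigma_{XX}^{1/2} w_X)\, r_{true}\,
#'   (\Sigma_{YY}^{1/2} w_Y)^\top \Sigma_{YY}^{1/2}}
#' with diagonal square roots, so that the first canonical correlation of
#' the assembled model is exactly \code{r_true} and the canonical weights
#' are \code{w_x}, \code{w_y}.
#'
#' @inheritParams build_pls_cross_cov
#' @param w_x,w_y weight vectors normalized to unit score variance.
#' @return The \code{p_x} by \code{p_y} cross-covariance matrix.
#' @export
build_cca_cross_cov <- function(w_x, w_y, r_true, sigma_xx, sigma_yy) {
  check_r_true(r_true)
  if (abs(sum(w_x^2 * sigma_xx) - 1) > 1e-8 ||
      abs(sum(w_y^2 * sigma_yy) - 1) > 1e-8) {
    stop("CCA weights must satisfy the unit score-variance normalization")
  }
  u <- sqrt(sigma_xx) * w_x              # Sigma_XX^{1/2} w_x, unit norm
  v <- sqrt(sigma_yy) * w_y
  (sqrt(sigma_xx) * u) %*% (r_true * t(sqrt(sigma_yy) * v))
}

check_r_true <- function(r_true) {
  if (length(r_true) != 1L || !is.finite(r_true) || r_true < 0 || r_true >= 1) {
    stop("'r_true' must lie in [0, 1)")
  }
  invisible(r_true)
}

#' Assemble the joint covariance matrix of a model
#'
#' Stacks the within-set blocks (diagonal, from the variance spectra) and
#' the between-set block into the full
#' \eqn{(p_X + p_Y) \times (p_X + p_Y)} covariance matrix of the
#' generative multivariate normal distribution.
#'
#' @param model a \code{cov_model} object.
#' @return Symmetric covariance matrix.
#' @export
joint_covariance <- function(model) {
  px <- length(model$sigma_xx)
  py <- length(model$sigma_yy)
  sigma <- matrix(0, px + py, px + py)
  sigma[seq_len(px), seq_len(px)] <- diag(model$sigma_xx, px)
  sigma[px + seq_len(py), px + seq_len(py)] <- diag(model$sigma_yy, py)
  sigma[seq_len(px), px + seq_len(py)] <- model$sigma_xy
  sigma[px + seq_len(py), seq_len(px)] <- t(model$sigma_xy)
  sigma
}

#' Generate a joint covariance model with a planted association mode
#'
#' Constructs the population covariance of two datasets in their principal
#' component coordinate systems: diagonal within-set blocks with power-law
#' variance spectra, and a rank-1 between-set block encoding a single true
#' association mode of strength \code{r_true} for either CCA or PLS.
#'
#' Candidate weight vectors are drawn uniformly from the unit sphere
#' (normalized standard normal vectors) and rejection-sampled until
#' (i) both pass the explained-variance admissibility criterion
#' ([admissible_weight()]) and (ii) the assembled joint covariance matrix is
#' positive definite (smallest eigenvalue \code{> 1e-10} times the largest).
#' For CCA the accepted unit vectors are then rescaled to unit score
#' variance ([normalize_cca_weight()]). Steep spectra combined with large
#' \code{r_true} can make the PLS construction infeasible; after
#' \code{max_tries} rejected proposals an error identifies the failing
#' constraint.
#'
#' @param p_x,p_y feature counts of the two sets.
#' @param a_x,a_y within-set spectrum decay exponents (\code{<= 0}).
#' @param r_true true between-set correlation in \code{[0, 1)}.
#' @param method \code{"cca"} or \code{"pls"}.
#' @param seed integer seed; the construction is deterministic given it.
#' @param c_x,c_y spectrum scale factors (default 1; they only rescale).
#' @param max_tries rejection-sampling cap (default 10000).
#' @return An object of class \code{cov_model} with elements
#'   \code{sigma_xx}, \code{sigma_yy}, \code{sigma_xy}, \code{w_x_true},
#'   \code{w_y_true}, \code{r_true}, \code{method}, \code{a_x}, \code{a_y},
#'   \code{seed_info} (seed plus number of rejected proposals).
#' @examples
#' m <- generate_model(4, 4, -1, -1, r_true = 0.3, method = "cca", seed = 1)
#' min(eigen(joint_covariance(m), symmetric = TRUE)$values) > 0
#' @export
generate_model <- function(p_x, p_y, a_x, a_y, r_true, method = c("cca", "pls"),
                           seed = 1L, c_x = 1, c_y = 1, max_tries = 10000L) {
  method <- match.arg(method)
  check_r_true(r_true)
  sigma_xx <- powerlaw_spectrum(p_x, a_x, c_x)
  sigma_yy <- powerlaw_spectrum(p_y, a_y, c_y)

  res <- with_seed(seed, {
    n_rejected <- 0L
    last_fail <- "admissibility"
    repeat {
      if (n_rejected >= max_tries) {
        stop(sprintf(
          "no admissible weight pair found after %d proposals (last failing constraint: %s); the parameter combination may be infeasible",
          max_tries, last_fail
        ))
      }
      u_x <- random_unit_vector(p_x)
      u_y <- random_unit_vector(p_y)
      if (!admissible_weight(u_x, sigma_xx) ||
          !admissible_weight(u_y, sigma_yy)) {
        n_rejected <- n_rejected + 1L
        last_fail <- "explained-variance admissibility"
        next
      }
      if (method == "cca") {
        w_x <- normalize_cca_weight(u_x, sigma_xx)
        w_y <- normalize_cca_weight(u_y, sigma_yy)
        sigma_xy <- build_cca_cross_cov(w_x, w_y, r_true, sigma_xx, sigma_yy)
      } else {
        w_x <- u_x
        w_y <- u_y
        sigma_xy <- build_pls_cross_cov(w_x, w_y, r_true, sigma_xx, sigma_yy)
      }
      model <- structure(
        list(sigma_xx = sigma_xx, sigma_yy = sigma_yy, sigma_xy = sigma_xy,
             w_x_true = w_x, w_y_true = w_y, r_true = r_true,
             method = method, a_x = a_x, a_y = a_y,
             seed_info = list(seed = as.integer(seed),
                              n_rejected = n_rejected)),
        class = "cov_model"
      )
      ev <- eigen(joint_covariance(model), symmetric = TRUE,
                  only.values = TRUE)$values
      if (min(ev) > 1e-10 * max(ev)) {
        model$seed_info$n_rejected <- n_rejected
        break
      }
      n_rejected <- n_rejected + 1L
      last_fail <- "positive definiteness of the joint covariance"
    }
    model
  })
  res
}

random_unit_vector <- function(p) {
  v <- stats::rnorm(p)
  v / sqrt(sum(v^2))
}

#' @export
print.cov_model <- function(x, ...) {
  cat(sprintf(
    "Joint covariance model (%s): p_x = %d, p_y = %d, r_true = %g, a_x = %g, a_y = %g\n",
    toupper(x$method), length(x$sigma_xx), length(x$sigma_yy),
    x$r_true, x$a_x, x$a_y
  ))
  cat(sprintf("  seed %d, %d rejected weight proposals\n",
              x$seed_info$seed, x$seed_info$n_rejected))
  invisible(x)
}

#' Draw a synthetic dataset pair from a covariance model
#'
#' Samples \code{n} observations from the zero-mean multivariate normal
#' distribution with the model's joint covariance and splits them into the
#' \code{X} and \code{Y} blocks. Data are expressed in each set's principal
#' component coordinate system, the generating convention of the model.
#'
#' @param model a \code{cov_model}.
#' @param n number of observations (\code{>= 2}).
#' @param seed integer seed; draws are deterministic given it.
#' @return A list of class \code{dataset_pair} with matrices \code{X}
#'   (\code{n} by \code{p_x}) and \code{Y} (\code{n} by \code{p_y}) and the
#'   observation count \code{n}.
#' @export
sample_dataset <- function(model, n, seed = 1L) {
  stopifnot(inherits(model, "cov_model"))
  if (length(n) != 1L || n < 2 || n != round(n)) {
    stop("'n' must be an integer >= 2")
  }
  px <- length(model$sigma_xx)
  py <- length(model$sigma_yy)
  ch <- model_chol(model)
  z <- with_seed(seed, matrix(stats::rnorm(n * (px + py)), n, px + py))
  d <- z %*% ch
  structure(
    list(X = d[, seq_len(px), drop = FALSE],
         Y = d[, px + seq_len(py), drop = FALSE],
         n = as.integer(n)),
    class = "dataset_pair"
  )
}

# Upper-triangular Cholesky factor of the joint covariance, cached on the
# model object in the caller's copy when assigned back; recomputed otherwise.
model_chol <- function(model) {
  if (!is.null(model$.chol)) return(model$.chol)
  chol(joint_covariance(model))
}

#' Cache the Cholesky factor of a model's joint covariance
#'
#' Sweeps draw many datasets from the same model; precomputing the
#' Cholesky factor once avoids refactorizing per draw.
#'
#' @param model a \code{cov_model}.
#' @return The model with the factor stored internally.
#' @export
precompute_sampler <- function(model) {
  model$.chol <- chol(joint_covariance(model))
  model
}

#' True (population) solution of a covariance model
#'
#' Returns the planted weights, the true between-set correlation, and the
#' population loadings: the correlation between each variable and the
#' mode's score, computed from the population covariance rather than a
#' sample. For variable \eqn{i} of set \eqn{X} the loading is
#' \deqn{\ell_i = (\Sigma_{XX} w_X)_i / \sqrt{\sigma_{XX,i}\, w_X^\top \Sigma_{XX} w_X}}
#'
#' @param model a \code{cov_model}.
#' @return A list with \code{w_x}, \code{w_y}, \code{loadings_x},
#'   \code{loadings_y}, \code{r_true}.
#' @export
true_solution <- function(model) {
  stopifnot(inherits(model, "cov_model"))
  list(
    w_x = model$w_x_true,
    w_y = model$w_y_true,
    loadings_x = population_loadings(model$w_x_true, model$sigma_xx),
    loadings_y = population_loadings(model$w_y_true, model$sigma_yy),
    r_true = model$r_true
  )
}

population_loadings <- function(w, sigma) {
  score_var <- sum(w^2 * sigma)
  (sigma * w) / sqrt(sigma * score_var)
}
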