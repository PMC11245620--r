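#' Calibrate the log-linear sample-size calculator
#'
#' Determining required sample sizes by simulation is expensive. The
#' calculator summarizes sweep outputs with an ordinary least squares fit of
#' \deqn{\log n_{req} = \beta_0 + \beta_1 \log r_{true} +
#'   \beta_2 \log(p_X + p_Y) + \beta_3 |a_X + a_Y|}
#' so that a required sample size can later be predicted from the three
#' model parameters alone. Rows with a "not reached" sentinel are excluded.
#'
#' @param estimates \code{data.frame} as returned by [required_from_sweep()]
#'   (columns \code{r_true}, \code{p_x}, \code{p_y}, \code{decay_sum},
#'   \code{combined_n}), or any frame with columns \code{r_true},
#'   \code{p_total}, \code{decay_sum}, \code{n_required}.
#' @param method method tag stored with the calculator.
#' @return Object of class \code{size_calculator} with \code{coefficients}
#'   (intercept, \code{log_r_true}, \code{log_p_total}, \code{abs_decay}),
#'   \code{r_squared}, \code{sigma_resid} and the calibration ranges.
#' @export
calibrate_calculator <- function(estimates, method = "cca") {
  d <- normalize_estimates(estimates)
  d <- d[is.finite(d$n_required) & d$r_true > 0, ]
  if (nrow(d) < 5) stop("need at least 5 usable sample-size estimates")
  fit <- stats::lm(log(n_required) ~ log(r_true) + log(p_total) + abs_decay,
                   data = d)
  if (anyNA(stats::coef(fit))) stop("collinear calibration design")
  structure(
    list(
      coefficients = stats::setNames(
        as.numeric(stats::coef(fit)),
        c("intercept", "log_r_true", "log_p_total", "abs_decay")),
      r_squared = summary(fit)$r.squared,
      sigma_resid = summary(fit)$sigma,
      n_points = nrow(d),
      method = method,
      ranges = list(r_true = range(d$r_true), p_total = range(d$p_total),
                    abs_decay = range(d$abs_decay))
    ),
    class = "size_calculator"
  )
}

normalize_estimates <- function(estimates) {
  if (!is.null(estimates$n_required)) {
    d <- data.frame(r_true = estimates$r_true,
                    p_total = estimates$p_total,
                    abs_decay = abs(estimates$decay_sum),
                    n_required = estimates$n_required)
  } else if (!is.null(estimates$combined_n)) {
    d <- data.frame(r_true = estimates$r_true,
                    p_total = estimates$p_x + estimates$p_y,
                    abs_decay = abs(estimates$decay_sum),
                    n_required = estimates$combined_n)
  } else {
    stop("'estimates' must contain 'combined_n' or 'n_required'")
  }
  d
}

#' @export
print.size_calculator <- function(x, ...) {
  cat(sprintf("Sample-size calculator (%s), %d calibration points, R^2 = %.3f\n",
              toupper(x$method), x$n_points, x$r_squared))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Predict a required sample size from the calculator
#'
#' Evaluates the exponentiated linear predictor of a calibrated
#' [calibrate_calculator()] model. A warning is raised when the query lies
#' outside the calibration ranges, where the log-linear summary is an
#' extrapolation.
#'
#' @param calculator a \code{size_calculator}.
#' @param r_true assumed true between-set correlation (\code{> 0}).
#' @param p_total total number of features across both sets.
#' @param decay_sum within-set spectrum decay sum \eqn{a_X + a_Y}
#'   (\code{<= 0}).
#' @return Predicted required sample size (numeric).
#' @export
predict_sample_size <- function(calculator, r_true, p_total, decay_sum) {
  stopifnot(inherits(calculator, "size_calculator"))
  if (any(r_true <= 0)) stop("'r_true' must be > 0")
  rg <- calculator$ranges
  if (any(r_true < rg$r_true[1] | r_true > rg$r_true[2]) ||
      any(p_total < rg$p_total[1] | p_total > rg$p_total[2]) ||
      any(abs(decay_sum) < rg$abs_decay[1] |
            abs(decay_sum) > rg$abs_decay[2])) {
    warning("query outside the calibration range; prediction is an extrapolation")
  }
  b <- calculator$coefficients
  exp(b["intercept"] + b["log_r_true"] * log(r_true) +
        b["log_p_total"] * log(p_total) + b["abs_decay"] * abs(decay_sum))
}

#' Retrospective weight-error estimation for a reported CCA
#'
#' Estimates how wrong the weight vectors of a published CCA are likely to
#' be, given only its sample size, feature counts and observed canonical
#' correlation. Synthetic datasets of the reported size are generated from
#' models with flat within-set spectra while sweeping the assumed true
#' correlation over a grid; datasets whose estimated canonical correlation
#' matches the reported one within a tolerance are retained, and their
#' known weight errors pooled into the estimate. The match tolerance starts
#' at 0.01 and doubles (up to 0.08) until at least \code{min_matches}
#' datasets match; if no dataset matches at the widest tolerance the
#' reported value is implausible under the model and an error is raised.
#'
#' @param n reported number of observations.
#' @param p_x,p_y reported feature counts.
#' @param r_observed reported canonical correlation in \code{[0, 1]}.
#' @param r_true_grid candidate true correlations (default 0 to 0.99 in
#'   steps of 0.01); one covariance model is generated per candidate.
#' @param n_per_r datasets drawn per candidate model (default 100).
#' @param min_matches matched datasets sought before the tolerance stops
#'   widening (default 50).
#' @param seed master seed.
#' @return Object of class \code{weight_error_estimate} with
#'   \code{matched_r_true_values}, \code{weight_error_samples},
#'   \code{tolerance} (final match tolerance) and \code{summary}
#'   (mean and 95% percentile interval).
#' @export
estimate_weight_error <- function(n, p_x, p_y, r_observed,
                                  r_true_grid = seq(0, 0.99, by = 0.01),
                                  n_per_r = 100L, min_matches = 50L,
                                  seed = 1L) {
  if (r_observed < 0 || r_observed > 1) stop("'r_observed' must be in [0, 1]")
  if (n < p_x + p_y) {
    warning("reported n is smaller than the total feature count")
  }
  if (n - 1 <= max(p_x, p_y)) {
    stop("reported n is too small for CCA (need n - 1 > max(p_x, p_y))")
  }
  r_hat <- numeric(0)
  w_err <- numeric(0)
  r_cand <- numeric(0)
  for (i in seq_along(r_true_grid)) {
    r <- r_true_grid[i]
    model <- generate_model(p_x, p_y, 0, 0, r, "cca",
                            seed = child_seed(seed, i, 0))
    model <- precompute_sampler(model)
    truth <- true_solution(model)
    for (j in seq_len(n_per_r)) {
      d <- sample_dataset(model, n, seed = child_seed(seed, i, j))
      fit <- fit_cca_pls(d$X, d$Y, "cca")
      r_hat <- c(r_hat, fit$assoc_strength)
      w_err <- c(w_err, weight_error(fit$w_x_hat, fit$w_y_hat,
                                     truth$w_x, truth$w_y))
      r_cand <- c(r_cand, r)
    }
  }
  tol <- 0.01
  repeat {
    matched <- abs(r_hat - r_observed) <= tol
    if (sum(matched) >= min_matches || tol >= 0.08) break
    tol <- tol * 2
  }
  if (!any(matched)) {
    stop(sprintf(
      "no synthetic dataset matched r_observed = %g within tolerance %.2f; the reported value is implausible at this n and dimensionality",
      r_observed, tol))
  }
  samples <- w_err[matched]
  structure(
    list(
      matched_r_true_values = r_cand[matched],
      weight_error_samples = samples,
      tolerance = tol,
      n_matched = sum(matched),
      summary = list(
        mean = mean(samples),
        interval = stats::quantile(samples, c(0.025, 0.975), names = FALSE)
      )
    ),
    class = "weight_error_estimate"
  )
}

#' @export
print.weight_error_estimate <- function(x, ...) {
  cat(sprintf(
    "Retrospective weight-error estimate: mean %.3f, 95%% interval [%.3f, %.3f]\n  (%d matched datasets, match tolerance %.2f)\n",
    x$summary$mean, x$summary$interval[1], x$summary$interval[2],
    x$n_matched, x$tolerance))
  invisible(x)
}

#' Read a table of reported CCA results
#'
#' Reads a delimited table with columns \code{n}, \code{p_x}, \code{p_y}
#' and \code{r_observed} describing CCA analyses reported in the
#' literature, for use with [estimate_weight_error()].
#'
#' @param path path to a CSV file with a header row.
#' @return \code{data.frame} with the four validated columns.
#' @export
read_reported_cca <- function(path) {
  d <- utils::read.csv(path)
  needed <- c("n", "p_x", "p_y", "r_observed")
  if (!all(needed %in% names(d))) {
    stop("reported-CCA table must have columns ", paste(needed, collapse = ", "))
  }
  if (any(d$r_observed < 0 | d$r_observed > 1)) {
    stop("'r_observed' values must lie in [0, 1]")
  }
  if (any(d$n < d$p_x + d$p_y)) {
    warning("some rows report fewer observations than total features")
  }
  d[needed]
}
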