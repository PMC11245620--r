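#' Define a parameter sweep grid
#'
#' Describes a factorial sweep over true between-set correlations, feature
#' space dimensionalities and spectrum decay sums, evaluated over a grid of
#' sample sizes. Sample sizes are specified as samples per feature
#' (\code{spf_values}, multiplied by the total feature count per
#' combination) or as explicit \code{n_values}. When neither is given, a
#' log-spaced samples-per-feature grid is chosen per \code{r_true}, from
#' the smallest size satisfying the CCA rank requirement up to a heuristic
#' maximum that grows as \code{r_true} shrinks.
#'
#' @param r_true_values true between-set correlations to sweep.
#' @param p_x_values,p_y_values feature counts, matched pairwise
#'   (\code{p_y_values} defaults to \code{p_x_values}).
#' @param decay_sums values of \eqn{a_X + a_Y}; each is split evenly between
#'   the two sets unless \code{decay_split} says otherwise.
#' @param spf_values samples-per-feature grid (log-spaced recommended), or
#'   \code{NULL} for the heuristic default.
#' @param n_values explicit sample-size grid overriding \code{spf_values}.
#' @param n_matrices number of covariance matrices (models with different
#'   true weights) per combination; default 25.
#' @param n_reps repeated dataset draws per model and sample size; default 100.
#' @param n_perm permutations for the significance test; default 1000.
#' @param method \code{"cca"} or \code{"pls"}.
#' @param alpha significance threshold for power; default 0.05.
#' @param decay_split fraction of the decay sum assigned to the X set
#'   (default 0.5, i.e. \code{a_x = a_y}).
#' @param master_seed master seed; every model, dataset and permutation
#'   stream is derived from it via [child_seed()].
#' @return A list of class \code{sweep_grid}.
#' @export
sweep_grid <- function(r_true_values, p_x_values, p_y_values = p_x_values,
                       decay_sums = -2, spf_values = NULL, n_values = NULL,
                       n_matrices = 25L, n_reps = 100L, n_perm = 1000L,
                       method = c("cca", "pls"), alpha = 0.05,
                       decay_split = 0.5, master_seed = 1L) {
  method <- match.arg(method)
  stopifnot(length(r_true_values) >= 1, length(p_x_values) >= 1,
            length(p_x_values) == length(p_y_values),
            length(decay_sums) >= 1, n_matrices >= 1, n_reps >= 1)
  for (r in r_true_values) check_r_true(r)
  if (any(decay_sums > 0)) stop("decay sums must be <= 0")
  if (!is.null(n_values) && any(diff(n_values) <= 0)) {
    stop("'n_values' must be strictly increasing")
  }
  if (!is.null(spf_values) && any(diff(spf_values) <= 0)) {
    stop("'spf_values' must be strictly increasing")
  }
  structure(
    list(r_true_values = r_true_values, p_x_values = as.integer(p_x_values),
         p_y_values = as.integer(p_y_values), decay_sums = decay_sums,
         spf_values = spf_values, n_values = n_values,
         n_matrices = as.integer(n_matrices), n_reps = as.integer(n_reps),
         n_perm = as.integer(n_perm), method = method, alpha = alpha,
         decay_split = decay_split, master_seed = as.integer(master_seed)),
    class = "sweep_grid"
  )
}

# Sample-size grid for one parameter combination. The heuristic upper end
# grows as r_true shrinks (more samples needed for weaker associations).
sweep_n_grid <- function(grid, r_true, p_total) {
  if (!is.null(grid$n_values)) return(as.integer(grid$n_values))
  spf <- grid$spf_values
  if (is.null(spf)) {
    spf_min <- max(4, ceiling((max(grid$p_x_values, grid$p_y_values) + 2) /
                                p_total))
    spf_max <- max(8 * spf_min, ceiling(10 / max(r_true, 0.05)^2))
    spf <- exp(seq(log(spf_min), log(spf_max), length.out = 6))
  }
  unique(as.integer(round(spf * p_total)))
}

#' Run a seeded parameter sweep
#'
#' For every combination of \code{r_true}, dimensionality pair and decay
#' sum, generates \code{n_matrices} covariance models (differing in their
#' random true weights), and for every sample size in the grid draws one
#' common test-set pair per model plus \code{n_reps} training datasets.
#' Each training dataset is fitted, permutation-tested, and scored against
#' the model's true solution, producing one row of metrics per
#' (combination, matrix, sample size, repetition). Model generation
#' failures (rejection cap exceeded) are logged and the affected cells
#' skipped, so infeasible corners of a grid do not abort the sweep.
#'
#' Per-cell weight stability (mean absolute cosine similarity across all
#' pairs of repetitions, averaged over the X and Y sets) is attached to
#' every row of the cell.
#'
#' @param grid a [sweep_grid()].
#' @param progress emit per-combination progress lines to stderr.
#' @return A \code{data.frame} of class \code{sweep_result} with key
#'   columns (\code{r_true}, \code{p_x}, \code{p_y}, \code{decay_sum},
#'   \code{n}, \code{matrix_index}, \code{rep_index}) and metric columns
#'   (\code{r_hat}, \code{delta_r}, \code{delta_w}, \code{delta_t},
#'   \code{delta_l}, \code{p_value}, \code{significant}, \code{stability},
#'   \code{pc1_sim_x}, \code{pc1_sim_y}). Skipped combinations are recorded
#'   in \code{attr(, "skipped")}.
#' @export
run_sweep <- function(grid, progress = FALSE) {
  stopifnot(inherits(grid, "sweep_grid"))
  combos <- expand.grid(dim_index = seq_along(grid$p_x_values),
                        r_true = grid$r_true_values,
                        decay_sum = grid$decay_sums,
                        KEEP.OUT.ATTRS = FALSE)
  rows <- list()
  skipped <- list()
  for (ci in seq_len(nrow(combos))) {
    r_true <- combos$r_true[ci]
    p_x <- grid$p_x_values[combos$dim_index[ci]]
    p_y <- grid$p_y_values[combos$dim_index[ci]]
    ds <- combos$decay_sum[ci]
    a_x <- ds * grid$decay_split
    a_y <- ds * (1 - grid$decay_split)
    n_grid <- sweep_n_grid(grid, r_true, p_x + p_y)
    if (progress) {
      message(sprintf("sweep: r_true=%g p=%d+%d decay=%g (%d sample sizes)",
                      r_true, p_x, p_y, ds, length(n_grid)))
    }
    for (mi in seq_len(grid$n_matrices)) {
      model <- tryCatch(
        generate_model(p_x, p_y, a_x, a_y, r_true, grid$method,
                       seed = child_seed(grid$master_seed, ci, mi, 0)),
        error = function(e) e
      )
      if (inherits(model, "error")) {
        skipped[[length(skipped) + 1L]] <- data.frame(
          r_true = r_true, p_x = p_x, p_y = p_y, decay_sum = ds,
          matrix_index = mi, reason = conditionMessage(model))
        next
      }
      model <- precompute_sampler(model)
      cell <- sweep_one_model(grid, model, ci, mi, n_grid)
      cell$r_true <- r_true; cell$p_x <- p_x; cell$p_y <- p_y
      cell$decay_sum <- ds; cell$matrix_index <- mi
      rows[[length(rows) + 1L]] <- cell
    }
  }
  if (length(rows) == 0) stop("no sweep cells completed")
  out <- do.call(rbind, rows)
  out <- out[, c("r_true", "p_x", "p_y", "decay_sum", "n", "matrix_index",
                 "rep_index", "r_hat", "delta_r", "delta_w", "delta_t",
                 "delta_l", "p_value", "significant", "stability",
                 "pc1_sim_x", "pc1_sim_y")]
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else NULL
  attr(out, "method") <- grid$method
  attr(out, "alpha") <- grid$alpha
  class(out) <- c("sweep_result", "data.frame")
  out
}

# All repetitions for one model across the sample-size grid.
sweep_one_model <- function(grid, model, ci, mi, n_grid) {
  truth <- true_solution(model)
  # for PLS the true association strength is the covariance-scale singular
  # value, not r_true itself
  true_assoc <- if (grid$method == "cca") {
    model$r_true
  } else {
    svd(model$sigma_xy, nu = 0, nv = 0)$d[1]
  }
  out <- vector("list", length(n_grid))
  for (ni in seq_along(n_grid)) {
    n <- n_grid[ni]
    test_pair <- sample_dataset(model, n,
                                seed = child_seed(grid$master_seed, ci, mi, 1, ni))
    true_tl_x <- test_loadings(test_pair$X, truth$w_x)
    true_tl_y <- test_loadings(test_pair$Y, truth$w_y)
    w_x_reps <- vector("list", grid$n_reps)
    w_y_reps <- vector("list", grid$n_reps)
    rec <- data.frame(
      n = rep.int(n, grid$n_reps), rep_index = seq_len(grid$n_reps),
      r_hat = NA_real_, delta_r = NA_real_, delta_w = NA_real_,
      delta_t = NA_real_, delta_l = NA_real_, p_value = NA_real_,
      significant = NA, stability = NA_real_,
      pc1_sim_x = NA_real_, pc1_sim_y = NA_real_
    )
    for (rep in seq_len(grid$n_reps)) {
      d <- sample_dataset(model, n,
                          seed = child_seed(grid$master_seed, ci, mi, 2, ni, rep))
      fit <- fit_cca_pls(d$X, d$Y, grid$method)
      pt <- permutation_test(d$X, d$Y, grid$method, n_perm = grid$n_perm,
                             seed = child_seed(grid$master_seed, ci, mi, 3, ni, rep))
      w_x_reps[[rep]] <- fit$w_x_hat
      w_y_reps[[rep]] <- fit$w_y_hat
      rec$r_hat[rep] <- fit$assoc_strength
      rec$delta_r[rep] <- relative_assoc_error(fit$assoc_strength, true_assoc)
      rec$delta_w[rep] <- weight_error(fit$w_x_hat, fit$w_y_hat,
                                       truth$w_x, truth$w_y)
      rec$delta_t[rep] <- score_error(fit$w_x_hat, fit$w_y_hat, truth, test_pair)
      rec$delta_l[rep] <- loading_error(
        test_loadings(test_pair$X, fit$w_x_hat),
        test_loadings(test_pair$Y, fit$w_y_hat),
        true_tl_x, true_tl_y)
      rec$p_value[rep] <- pt$p_value
      rec$significant[rep] <- pt$p_value < grid$alpha
      rec$pc1_sim_x[rep] <- pc1_similarity(fit$w_x_hat)
      rec$pc1_sim_y[rep] <- pc1_similarity(fit$w_y_hat)
    }
    rec$stability <- if (grid$n_reps >= 2) {
      (stability(w_x_reps) + stability(w_y_reps)) / 2
    } else {
      NA_real_
    }
    out[[ni]] <- rec
  }
  do.call(rbind, out)
}

#' Aggregate a sweep into per-sample-size metric curves
#'
#' Averages the metric columns across repetitions and covariance matrices
#' for each parameter combination and sample size. The relative
#' association-strength error is averaged with its sign (it measures a
#' bias, and random over/under-estimation across draws cancels); the
#' combined sample-size criterion later bounds its magnitude. Power is the
#' fraction of significant repetitions.
#'
#' @param result a \code{sweep_result}.
#' @return \code{data.frame} with one row per (combination, n) and columns
#'   \code{power}, \code{delta_r_mean}, \code{delta_w}, \code{delta_t},
#'   \code{delta_l}, \code{stability}, \code{pc1_sim_x}, \code{pc1_sim_y},
#'   \code{n_cells}.
#' @export
aggregate_sweep <- function(result) {
  stopifnot(inherits(result, "sweep_result") || is.data.frame(result))
  key <- interaction(result$r_true, result$p_x, result$p_y,
                     result$decay_sum, result$n, drop = TRUE)
  agg <- lapply(split(seq_len(nrow(result)), key), function(idx) {
    s <- result[idx, ]
    data.frame(
      r_true = s$r_true[1], p_x = s$p_x[1], p_y = s$p_y[1],
      decay_sum = s$decay_sum[1], n = s$n[1],
      power = mean(s$significant),
      delta_r_mean = mean(s$delta_r),
      delta_w = mean(s$delta_w),
      delta_t = mean(s$delta_t),
      delta_l = mean(s$delta_l),
      stability = mean(s$stability),
      pc1_sim_x = mean(s$pc1_sim_x),
      pc1_sim_y = mean(s$pc1_sim_y),
      n_cells = length(idx)
    )
  })
  out <- do.call(rbind, agg)
  out <- out[order(out$r_true, out$p_x, out$p_y, out$decay_sum, out$n), ]
  rownames(out) <- NULL
  out
}

#' Required sample size from a metric curve
#'
#' Interpolates mean metric values against \code{log(n)} with a natural
#' cubic spline and returns the smallest sample size at which the metric
#' crosses the target and stays on the acceptable side for all larger
#' simulated sizes. Metrics are occasionally non-monotonic through Monte
#' Carlo noise; candidate roots around which the spline fluctuates strongly
#' (total variation within half a grid step exceeding twice the target
#' margin) are discarded as noise. If the target is met at every simulated
#' size the smallest simulated size is returned; if it is never met (or all
#' roots are filtered out) the result is \code{NA}, the "not reached"
#' sentinel.
#'
#' @param n vector of simulated sample sizes (at least 4, increasing).
#' @param values mean metric values at each \code{n}.
#' @param target target level (0.9 for power, 0.1 for the error metrics).
#' @param better \code{"lower"} if smaller metric values are better
#'   (errors), \code{"higher"} for power.
#' @return Required sample size (numeric), or \code{NA_real_}.
#' @examples
#' n <- c(16, 25, 64, 144, 400)
#' required_sample_size(n, 1 / sqrt(n), target = 0.1, better = "lower")
#' @export
required_sample_size <- function(n, values, target,
                                 better = c("lower", "higher")) {
  better <- match.arg(better)
  if (length(n) < 4) stop("need at least 4 grid points for a cubic spline")
  if (length(values) != length(n)) stop("'n' and 'values' lengths differ")
  ord <- order(n)
  n <- n[ord]; values <- values[ord]
  meets <- if (better == "lower") values <= target else values >= target
  if (all(meets)) return(as.numeric(n[1]))
  if (!meets[length(meets)]) return(NA_real_)

  x <- log(n)
  f <- stats::splinefun(x, values, method = "natural")
  g <- function(z) if (better == "lower") f(z) - target else target - f(z)
  # g > 0 means the target is not met; look for downward crossings
  dense <- seq(x[1], x[length(x)], length.out = 512L)
  gd <- g(dense)
  cross <- which(gd[-length(gd)] > 0 & gd[-1] <= 0)
  if (length(cross) == 0) return(NA_real_)
  roots <- vapply(cross, function(i) {
    stats::uniroot(g, lower = dense[i], upper = dense[i + 1],
                   tol = 1e-10)$root
  }, numeric(1))

  margin <- min(target, 1 - target)
  half_step <- mean(diff(x)) / 2
  ok <- vapply(roots, function(r) {
    lo <- max(x[1], r - half_step)
    hi <- min(x[length(x)], r + half_step)
    z <- seq(lo, hi, length.out = 64L)
    fz <- f(z)
    # wiggle: total variation in excess of the net change; a steep but
    # monotone crossing has none
    wiggle <- sum(abs(diff(fz))) - abs(fz[length(fz)] - fz[1])
    wiggle <= 2 * margin
  }, logical(1))
  roots <- roots[ok]
  if (length(roots) == 0) return(NA_real_)

  for (r in sort(roots)) {
    later <- n > exp(r)
    if (all(meets[later])) return(exp(r))
  }
  NA_real_
}

#' Combined required sample size over the five evaluation metrics
#'
#' The combined criterion requires at least 90% power and at most 10%
#' error simultaneously for the association strength, weights, scores and
#' loadings; the required sample size is the maximum of the five per-metric
#' requirements. A "not reached" sentinel (\code{NA}) in any metric
#' propagates to the combined value.
#'
#' @param per_metric named list or vector with entries \code{power},
#'   \code{delta_r}, \code{delta_w}, \code{delta_t}, \code{delta_l}.
#' @return A list with \code{per_metric_n} and \code{combined_n}.
#' @export
combined_sample_size <- function(per_metric) {
  needed <- c("power", "delta_r", "delta_w", "delta_t", "delta_l")
  per_metric <- as.list(per_metric)
  if (!all(needed %in% names(per_metric))) {
    stop("missing per-metric entries: ",
         paste(setdiff(needed, names(per_metric)), collapse = ", "))
  }
  vals <- unlist(per_metric[needed])
  combined <- if (anyNA(vals)) NA_real_ else max(vals)
  list(per_metric_n = as.list(vals), combined_n = combined)
}

#' Required sample sizes for every combination of a sweep
#'
#' Applies the spline interpolation and the combined five-metric criterion
#' to an aggregated sweep: power is targeted at \code{>= 0.9} and the four
#' error metrics at \code{<= 0.1}.
#'
#' @param result a \code{sweep_result} or the output of [aggregate_sweep()].
#' @param power_target,error_target targets for power and errors.
#' @return \code{data.frame} with one row per parameter combination,
#'   per-metric required sample sizes (\code{n_power}, \code{n_delta_r},
#'   \code{n_delta_w}, \code{n_delta_t}, \code{n_delta_l}), the
#'   \code{combined_n}, and \code{combined_spf} (combined divided by the
#'   total feature count).
#' @export
required_from_sweep <- function(result, power_target = 0.9,
                                error_target = 0.1) {
  agg <- if (!is.null(result$delta_r_mean)) result else aggregate_sweep(result)
  key <- interaction(agg$r_true, agg$p_x, agg$p_y, agg$decay_sum, drop = TRUE)
  rows <- lapply(split(seq_len(nrow(agg)), key), function(idx) {
    s <- agg[idx, ]
    s <- s[order(s$n), ]
    per <- list(
      power = required_sample_size(s$n, s$power, power_target, "higher"),
      delta_r = required_sample_size(s$n, abs(s$delta_r_mean), error_target,
                                     "lower"),
      delta_w = required_sample_size(s$n, s$delta_w, error_target, "lower"),
      delta_t = required_sample_size(s$n, s$delta_t, error_target, "lower"),
      delta_l = required_sample_size(s$n, s$delta_l, error_target, "lower")
    )
    comb <- combined_sample_size(per)
    data.frame(
      r_true = s$r_true[1], p_x = s$p_x[1], p_y = s$p_y[1],
      decay_sum = s$decay_sum[1],
      n_power = per$power, n_delta_r = per$delta_r, n_delta_w = per$delta_w,
      n_delta_t = per$delta_t, n_delta_l = per$delta_l,
      combined_n = comb$combined_n,
      combined_spf = comb$combined_n / (s$p_x[1] + s$p_y[1])
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
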