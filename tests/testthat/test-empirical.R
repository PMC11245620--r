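test_that("deconfounding removes linear confound contributions", {
  set.seed(60)
  n <- 50
  data <- matrix(rnorm(n * 4), n)
  # intercept-only confound: plain column centering
  ones <- matrix(1, n, 1)
  expect_equal(deconfound(data, ones), scale(data, scale = FALSE),
               ignore_attr = TRUE)
  # residuals orthogonal to arbitrary confounds
  C <- cbind(1, matrix(rnorm(n * 3), n))
  out <- deconfound(data, C)
  expect_lt(max(abs(crossprod(C, out))), 1e-8)
  # already-orthogonal data pass through unchanged
  expect_equal(deconfound(out, C), out, tolerance = 1e-10)
  expect_warning(deconfound(data, cbind(C, C[, 2])), "rank deficient")
  expect_error(deconfound(data, C[1:10, ]), "row counts")
})

test_that("inverse normal transform is monotone, centered and tie-stable", {
  x <- c(3, 1, 2)
  y <- inverse_normal_transform(x)
  expect_equal(order(y), order(x))
  expect_equal(mean(y), 0, tolerance = 1e-12)
  # symmetric input maps to an antisymmetric result
  xs <- c(-5, -1, 0, 1, 5)
  ys <- inverse_normal_transform(xs)
  expect_equal(ys, -rev(ys), tolerance = 1e-12)
  # ties share a transformed value; missing entries are preserved
  xt <- c(1, 2, 2, 3, NA)
  yt <- inverse_normal_transform(xt)
  expect_equal(yt[2], yt[3])
  expect_true(is.na(yt[5]))
  expect_error(inverse_normal_transform(c(1, 1, 1, 1)), "constant")
  expect_error(inverse_normal_transform(c(1, 2, NA, NA)), "3 non-missing")
})

test_that("PCA reduction returns eigenvalue-scaled orthogonal scores", {
  set.seed(61)
  base <- matrix(rnorm(30 * 2), 30)
  data <- base %*% matrix(rnorm(2 * 6), 2)  # exact rank 2
  sc <- pca_reduce(data, 2)
  rot <- attr(sc, "rotation")
  recon <- sc %*% t(rot[, 1:2])
  expect_equal(recon, scale(data, scale = FALSE), ignore_attr = TRUE,
               tolerance = 1e-8)
  vars <- apply(pca_reduce(matrix(rnorm(40 * 5), 40), 5), 2, var)
  expect_true(all(diff(vars) <= 1e-12))
  cp <- crossprod(pca_reduce(matrix(rnorm(40 * 5), 40), 3))
  expect_lt(max(abs(cp[upper.tri(cp)])), 1e-8)
  expect_error(pca_reduce(data, 31), "exceeds")
})

test_that("nearest positive definite repair is minimal and idempotent", {
  expect_equal(nearest_positive_definite(diag(3)), diag(3))
  m <- diag(c(1, -0.1))
  fixed <- nearest_positive_definite(m)
  ev <- eigen(fixed, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
  # eigenvalue clipping bound on the Frobenius distance
  expect_lte(norm(fixed - m, "F"), 0.1 + 1e-6)
  expect_error(nearest_positive_definite(matrix(1, 2, 3)), "square")
  expect_error(nearest_positive_definite(matrix(c(1, 2, 0, 1), 2)), "symmetric")
})

test_that("pairwise-complete covariance handles missingness and feeds PD repair", {
  set.seed(62)
  data <- matrix(rnorm(8 * 20), 8)  # 8 observations, 20 variables
  expect_equal(pairwise_complete_covariance(data), cov(t(data)))
  masked <- data
  masked[sample(length(masked), 40)] <- NA
  pc <- pairwise_complete_covariance(masked)
  expect_equal(pc, t(pc))
  # masking a variable in neither member of a pair leaves their entry alone
  m2 <- data
  m2[1, 3] <- NA
  pc2 <- pairwise_complete_covariance(m2)
  expect_equal(pc2[2, 4], cov(t(data))[2, 4])
  # end to end: repair yields a proper covariance matrix
  fixed <- nearest_positive_definite(pc)
  expect_gt(min(eigen(fixed, symmetric = TRUE, only.values = TRUE)$values), 0)
  allna <- data
  allna[1, ] <- NA
  expect_error(pairwise_complete_covariance(allna), "fewer than 2")
})

test_that("spectrum decay estimation respects the coverage cutoff", {
  expect_equal(spectrum_decay(powerlaw_spectrum(30, -1.5), 0.9), -1.5,
               tolerance = 1e-10)
  expect_equal(spectrum_decay(rep(2, 10), 0.3), 0, tolerance = 1e-12)
  # components beyond the coverage cutoff do not matter
  v <- powerlaw_spectrum(30, -2)
  k <- which(cumsum(v) / sum(v) >= 0.9)[1]
  v2 <- v
  v2[(k + 1):30] <- rev(v2[(k + 1):30])
  expect_equal(spectrum_decay(v2, 0.9), spectrum_decay(v, 0.9))
})

test_that("the subsampling audit reproduces convergence trends on synthetic data", {
  m <- generate_model(4, 4, -1, -1, 0.5, "cca", seed = 63)
  d <- sample_dataset(m, 600, seed = 64)
  sc <- subsampled_stability_analysis(d$X, d$Y, "cca", n_sizes = 3,
                                      n_reps = 8, n_perm = 20, seed = 65)
  expect_true(all(sc$sizes <= 300))
  cv <- sc$curve
  # in-sample estimates deflate and cross-validated ones inflate toward the
  # truth as the subsample grows
  expect_lt(cv$assoc_in[nrow(cv)], cv$assoc_in[1])
  expect_gt(cv$assoc_cv[nrow(cv)], cv$assoc_cv[1])
  expect_gt(cv$weight_stability[nrow(cv)], cv$weight_stability[1])
  sc2 <- subsampled_stability_analysis(d$X, d$Y, "cca", n_sizes = 3,
                                       n_reps = 8, n_perm = 20, seed = 65)
  expect_identical(sc$records, sc2$records)
  expect_error(
    subsampled_stability_analysis(d$X[1:30, ], d$Y[1:30, ], "cca",
                                  min_size = 100),
    "disjoint")
})

test_that("null data stay at the permutation-null association level", {
  m0 <- null_model(seed = 66)
  d <- sample_dataset(m0, 400, seed = 67)
  sc <- subsampled_stability_analysis(d$X, d$Y, "cca", n_sizes = 2,
                                      n_reps = 10, n_perm = 30, seed = 68)
  # in-sample association is statistically indistinguishable from the null
  delta <- sc$records$assoc_in - sc$records$null_mean
  expect_lt(abs(mean(delta)), 3 * sd(delta) / sqrt(length(delta)) + 0.05)
})

test_that("empirical-style fixtures carry confounds, missingness and truth", {
  m <- tiny_model("cca", seed = 70)
  fx <- generate_empirical_fixture(m, 300, q_confounds = 3,
                                   missing_rate = 0.2, seed = 71)
  expect_lt(abs(mean(is.na(fx$y$data)) - 0.2), 0.03)
  expect_false(anyNA(fx$x$data))
  # zero confound strength and no missingness reduce to a plain draw
  fx0 <- generate_empirical_fixture(m, 50, q_confounds = 2, missing_rate = 0,
                                    seed = 72, confound_strength = 0)
  expect_equal(fx0$x$data, sample_dataset(m, 50, seed = child_seed(72, 1))$X)
  expect_error(generate_empirical_fixture(m, 50, missing_rate = 0.7),
               "missing_rate")
})

test_that("deconfounding a fixture recovers the planted association", {
  m <- generate_model(8, 8, -1, -1, 0.3, "cca", seed = 73)
  errs <- vapply(c(5, 50), function(spf) {
    mean(vapply(1:5, function(i) {
      fx <- generate_empirical_fixture(m, spf * 16, q_confounds = 3,
                                       missing_rate = 0,
                                       seed = child_seed(73, spf, i))
      X <- deconfound(fx$x$data, fx$x$confounds)
      Y <- deconfound(fx$y$data, fx$y$confounds)
      f <- fit_cca_pls(X, Y, "cca")
      weight_error(f$w_x_hat, f$w_y_hat, m$w_x_true, m$w_y_true)
    }, numeric(1)))
  }, numeric(1))
  expect_gte(errs[1], 0.5)   # 5 samples per feature: unusable weights
  expect_lte(errs[2], 0.2)   # 50 samples per feature: accurate weights
})
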