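test_that("power-law spectrum follows the c * i^a form and rejects bad input", {
  expect_equal(powerlaw_spectrum(4, 0), rep(1, 4))
  expect_equal(powerlaw_spectrum(3, -1), c(1, 1 / 2, 1 / 3))
  expect_equal(powerlaw_spectrum(2, -2, c = 4), c(4, 1))
  expect_error(powerlaw_spectrum(0, -1), "positive integer")
  expect_error(powerlaw_spectrum(3, 0.5), "<= 0")
  expect_error(powerlaw_spectrum(3, -1, c = -2), "positive")
})

test_that("log-log regression on a power-law spectrum recovers the exponent", {
  for (a in c(-0.3, -1, -2.5)) {
    expect_equal(spectrum_decay(powerlaw_spectrum(20, a), coverage = 0.9), a,
                 tolerance = 1e-10)
  }
})

test_that("explained-variance admissibility matches the half-average-PC rule", {
  # flat spectrum: any unit vector explains exactly the average PC variance
  w <- c(1, 1, 1, 1) / 2
  expect_true(admissible_weight(w, rep(1, 4)))
  expect_false(admissible_weight(c(0, 1), c(4, 1)))  # 1 < 2.5/2
  expect_true(admissible_weight(c(1, 0), c(4, 1)))   # 4 > 1.25
  expect_error(admissible_weight(c(1, 0, 0), c(1, 1)), "same length")
})

test_that("CCA weight normalization yields unit score variance", {
  w <- c(1, 0) / 1
  expect_equal(normalize_cca_weight(w, c(1, 1)), w)
  expect_equal(normalize_cca_weight(1, 4), 0.5)
  set.seed(42)
  for (i in 1:20) {
    p <- sample(2:12, 1)
    w <- rnorm(p)
    sigma <- runif(p, 0.1, 5)
    wn <- normalize_cca_weight(w, sigma)
    expect_equal(sum(wn^2 * sigma), 1, tolerance = 1e-12)
  }
  expect_error(normalize_cca_weight(c(0, 0), c(1, 1)), "nonzero")
})

test_that("PLS cross-covariance has the prescribed singular structure", {
  expect_equal(build_pls_cross_cov(c(1, 0), c(0, 1), 0, c(1, 1), c(1, 1)),
               matrix(0, 2, 2))
  m <- build_pls_cross_cov(c(1, 0), c(1, 0), 0.3, c(1, 1), c(1, 1))
  expect_equal(m, matrix(c(0.3, 0, 0, 0), 2, 2))
  # s = r * sqrt(var_x * var_y) evaluated by hand
  m2 <- build_pls_cross_cov(c(1, 0), 1, 0.5, c(4, 1), 1)
  sv <- svd(m2)
  expect_equal(sv$d[1], 1.0, tolerance = 1e-12)
  expect_equal(abs(sv$u[, 1]), c(1, 0))
  expect_error(build_pls_cross_cov(c(2, 0), c(1, 0), 0.3, c(1, 1), c(1, 1)),
               "unit-norm")
})

test_that("CCA cross-covariance reproduces r_true under whitened SVD", {
  # identity within-set covariance: construction reduces to r * w_x w_y^T
  wx <- normalize_cca_weight(c(3, 4), c(1, 1))
  wy <- normalize_cca_weight(c(1, 1), c(1, 1))
  expect_equal(build_cca_cross_cov(wx, wy, 0.4, c(1, 1), c(1, 1)),
               0.4 * tcrossprod(wx, wy))
  expect_equal(build_cca_cross_cov(wx, wy, 0, c(1, 1), c(1, 1)),
               matrix(0, 2, 2))
  # random admissible weights: whitened SVD oracle returns r_true
  set.seed(7)
  for (i in 1:10) {
    p <- sample(2:8, 1)
    sx <- powerlaw_spectrum(p, -1)
    sy <- powerlaw_spectrum(p, -0.5)
    wx <- normalize_cca_weight(rnorm(p), sx)
    wy <- normalize_cca_weight(rnorm(p), sy)
    sxy <- build_cca_cross_cov(wx, wy, 0.3, sx, sy)
    k <- diag(1 / sqrt(sx)) %*% sxy %*% diag(1 / sqrt(sy))
    expect_equal(svd(k)$d[1], 0.3, tolerance = 1e-10)
  }
  expect_error(build_cca_cross_cov(c(1, 1), wy, 0.3, c(1, 1), c(1, 1)),
               "normalization")
})

test_that("generated models are positive definite, admissible and reproducible", {
  m1 <- generate_model(2, 2, 0, 0, 0.3, "pls", seed = 0)
  ev <- eigen(joint_covariance(m1), symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
  m2 <- generate_model(2, 2, 0, 0, 0.3, "pls", seed = 0)
  expect_identical(m1, m2)

  # PD and weight-constraint invariants over random parameter draws
  set.seed(99)
  for (i in 1:100) {
    p_x <- sample(c(2, 4, 8, 16), 1)
    p_y <- sample(c(2, 4, 8), 1)
    ds <- runif(1, -3, 0)
    cfrac <- runif(1)
    method <- sample(c("cca", "pls"), 1)
    r <- runif(1, 0, 0.7)
    m <- generate_model(p_x, p_y, ds * cfrac, ds * (1 - cfrac), r, method,
                        seed = i)
    sig <- joint_covariance(m)
    ev <- eigen(sig, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), 1e-10 * max(ev))
    expect_equal(qr(m$sigma_xy)$rank, if (r > 0) 1L else 0L)
    if (method == "pls") {
      expect_equal(sum(m$w_x_true^2), 1, tolerance = 1e-12)
    } else {
      expect_equal(sum(m$w_x_true^2 * m$sigma_xx), 1, tolerance = 1e-12)
    }
    # admissibility holds for the unit direction of the planted weight
    ux <- m$w_x_true / sqrt(sum(m$w_x_true^2))
    expect_true(admissible_weight(ux, m$sigma_xx))
  }
})

test_that("rejection-sampling provenance is recorded and the cap errors", {
  m <- generate_model(8, 8, -2, -2, 0.3, "pls", seed = 3)
  expect_gte(m$seed_info$n_rejected, 0)
  expect_error(
    generate_model(8, 8, -3, -3, 0.95, "pls", seed = 1, max_tries = 50),
    "infeasible|constraint"
  )
})

test_that("sampled datasets match the model distribution and are deterministic", {
  m <- generate_model(2, 2, -1, -1, 0.5, "cca", seed = 4)
  d <- sample_dataset(m, 1e5, seed = 5)
  expect_identical(dim(d$X), c(1e5L, 2L))
  sds <- sqrt(diag(joint_covariance(m)))
  expect_true(all(abs(colMeans(cbind(d$X, d$Y))) < 4 * sds / sqrt(1e5)))
  emp <- cov(cbind(d$X, d$Y))
  expect_lt(max(abs(emp - joint_covariance(m))), 0.05)
  d2 <- sample_dataset(m, 1e5, seed = 5)
  expect_identical(d, d2)
  expect_error(sample_dataset(m, 1), ">= 2")
})

test_that("true solution exposes population loadings in [-1, 1]", {
  m <- tiny_model("cca", p = 3, a = 0, r_true = 0.3, seed = 2)
  # flat spectrum: loadings are the unit-normalized weights
  w <- c(1, 1, 0) / sqrt(2)
  expect_equal(true_solution(m)$loadings_x,
               m$w_x_true / sqrt(sum(m$w_x_true^2)), tolerance = 1e-12)
  m2 <- m
  m2$w_x_true <- w
  ts <- true_solution(m2)
  expect_equal(ts$loadings_x, c(sqrt(2) / 2, sqrt(2) / 2, 0))
  for (mm in list(tiny_model("cca", seed = 6), tiny_model("pls", seed = 6))) {
    ts <- true_solution(mm)
    expect_true(all(abs(c(ts$loadings_x, ts$loadings_y)) <= 1 + 1e-12))
  }
})

test_that("model JSON and dataset CSV round-trip exactly", {
  m <- tiny_model("pls", seed = 8)
  f <- withr::local_tempfile(fileext = ".json")
  write_model_json(m, f)
  m2 <- read_model_json(f)
  expect_equal(m2$sigma_xy, m$sigma_xy, tolerance = 1e-15)
  expect_equal(m2$w_x_true, m$w_x_true, tolerance = 1e-15)
  expect_identical(m2$method, m$method)

  d <- sample_dataset(m, 20, seed = 1)
  fc <- withr::local_tempfile(fileext = ".csv")
  write_dataset_csv(d, fc)
  d2 <- read_dataset_csv(fc)
  expect_equal(unname(d2$X), unname(d$X), tolerance = 1e-12)
  expect_equal(unname(d2$Y), unname(d$Y), tolerance = 1e-12)
})
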