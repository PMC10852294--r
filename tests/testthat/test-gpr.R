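# The independent oracle throughout this file is dense linear algebra with
# explicit matrix inversion (solve()), which the implementation itself never
# uses: predictions and evidence must agree with it to tight tolerance.

dense_oracle <- function(X, y, Xs, th1, th2, sn) {
  K <- th1 * exp(-as.matrix(dist(X))^2 / th2) + diag(sn^2, nrow(X))
  Ks <- th1 * exp(-outer(seq_len(nrow(X)), seq_len(nrow(Xs)),
                         Vectorize(function(i, j) {
                           sum((X[i, ] - Xs[j, ])^2)
                         })) / th2)
  Kinv <- solve(K)
  list(mean = drop(crossprod(Ks, Kinv %*% y)),
       var = th1 - diag(crossprod(Ks, Kinv %*% Ks)),
       logml = drop(-0.5 * t(y) %*% Kinv %*% y -
                      0.5 * as.numeric(determinant(K)$modulus) -
                      0.5 * nrow(X) * log(2 * pi)))
}

test_that("the Gaussian kernel has its closed-form values and symmetry", {
  x <- c(1, 2, 3)
  expect_equal(gpr_kernel(x, x, theta1 = 2.5, theta2 = 1), 2.5)
  expect_equal(gpr_kernel(0, 1, theta1 = 1, theta2 = 1), exp(-1))
  set.seed(8)
  for (i in 1:10) {
    a <- stats::rnorm(4); b <- stats::rnorm(4)
    expect_identical(gpr_kernel(a, b, 1.3, 0.7), gpr_kernel(b, a, 1.3, 0.7))
  }
  expect_error(gpr_kernel(1:2, 1:3, 1, 1), "length mismatch")
  expect_error(gpr_kernel(1, 1, -1, 1), "positive")
})

test_that("the multiplicative kernel reading is available", {
  expect_equal(gpr_kernel(0, 1, 1, 2, theta2_multiplies = TRUE), exp(-2))
  m <- gpr_fit(matrix(c(0, 1)), c(0, 1),
               hyper = list(theta1 = 1, theta2 = 2, sigma_n = 0.1),
               theta2_multiplies = TRUE)
  p <- gpr_predict(m, matrix(0.5))
  K <- matrix(c(1, exp(-2 * 1), exp(-2 * 1), 1), 2) + diag(0.01, 2)
  ks <- exp(-2 * 0.25) * c(1, 1)
  expect_equal(p$mean, drop(ks %*% solve(K) %*% c(0, 1)), tolerance = 1e-10)
})

test_that("a single noiseless observation is interpolated exactly", {
  m <- gpr_fit(matrix(2), 5,
               hyper = list(theta1 = 3, theta2 = 1, sigma_n = 0))
  p <- gpr_predict(m, matrix(2))
  expect_equal(p$mean, 5, tolerance = 1e-9)
  expect_equal(p$variance, 0, tolerance = 1e-9)
})

test_that("the two-point hand case matches explicit 2x2 inversion", {
  X <- matrix(c(0, 1)); y <- c(0, 1)
  m <- gpr_fit(X, y, hyper = list(theta1 = 1, theta2 = 1, sigma_n = 0))
  p <- gpr_predict(m, matrix(0.5))
  K <- matrix(c(1, exp(-1), exp(-1), 1), 2)
  kstar <- c(exp(-0.25), exp(-0.25))
  expect_equal(p$mean, drop(kstar %*% solve(K) %*% y), tolerance = 1e-10)
  expect_equal(p$variance, 1 - drop(kstar %*% solve(K) %*% kstar),
               tolerance = 1e-8)
})

test_that("predictions match the dense-inverse oracle to 1e-8", {
  set.seed(21)
  X <- matrix(stats::rnorm(100), 20, 5)
  y <- stats::rnorm(20)
  Xs <- matrix(stats::rnorm(25), 5, 5)
  for (hp in list(c(1, 2, 0.1), c(3, 10, 0.01))) {
    m <- gpr_fit(X, y, hyper = list(theta1 = hp[1], theta2 = hp[2],
                                    sigma_n = hp[3]))
    p <- gpr_predict(m, Xs)
    o <- dense_oracle(X, y, Xs, hp[1], hp[2], hp[3])
    expect_equal(p$mean, o$mean, tolerance = 1e-8)
    expect_equal(p$variance, o$var, tolerance = 1e-8)
  }
})

test_that("noiseless training points are reproduced and far points revert to the prior", {
  set.seed(3)
  X <- matrix(stats::rnorm(30), 10, 3)
  y <- stats::rnorm(10)
  m <- gpr_fit(X, y, hyper = list(theta1 = 2, theta2 = 5, sigma_n = 0))
  p <- gpr_predict(m, X)
  expect_equal(p$mean, y, tolerance = 1e-6)
  far <- gpr_predict(m, matrix(50, 1, 3))
  expect_equal(far$mean, 0, tolerance = 1e-9)
  expect_equal(far$variance, 2, tolerance = 1e-9)
  expect_equal(far$k_starstar, 2)
  expect_error(gpr_predict(m, matrix(0, 1, 2)), "dimension mismatch")
})

test_that("log marginal likelihood matches closed form and the dense oracle", {
  m1 <- gpr_fit(matrix(0), 0,
                hyper = list(theta1 = 1, theta2 = 1, sigma_n = 0))
  expect_equal(gpr_log_marginal(m1), -0.5 * log(2 * pi), tolerance = 1e-10)
  set.seed(14)
  for (i in 1:3) {
    X <- matrix(stats::rnorm(20), 10, 2)
    y <- stats::rnorm(10)
    m <- gpr_fit(X, y, hyper = list(theta1 = 1.5, theta2 = 3, sigma_n = 0.2))
    o <- dense_oracle(X, y, X, 1.5, 3, 0.2)
    expect_equal(gpr_log_marginal(m), o$logml, tolerance = 1e-8)
  }
})

test_that("log marginal likelihood is invariant to row order", {
  set.seed(15)
  X <- matrix(stats::rnorm(24), 12, 2)
  y <- stats::rnorm(12)
  hp <- list(theta1 = 1, theta2 = 2, sigma_n = 0.1)
  perm <- sample(12)
  expect_equal(gpr_log_marginal(gpr_fit(X, y, hyper = hp)),
               gpr_log_marginal(gpr_fit(X[perm, ], y[perm], hyper = hp)),
               tolerance = 1e-9)
})

test_that("optimization does not end below its starting evidence", {
  set.seed(9)
  X <- matrix(stats::rnorm(40), 20, 2)
  y <- sin(X[, 1]) + 0.1 * stats::rnorm(20)
  m_opt <- gpr_fit(X, y, hyper = "optimize", seed = 4)
  # data-driven start that seeds the optimizer
  d2 <- as.matrix(dist(X))^2
  start <- list(theta1 = stats::var(y),
                theta2 = stats::median(d2[upper.tri(d2) & d2 > 0]),
                sigma_n = 0.1 * stats::sd(y))
  m_start <- gpr_fit(X, y, hyper = start)
  expect_gte(gpr_log_marginal(m_opt), gpr_log_marginal(m_start) - 1e-6)
})

test_that("adding a training point never increases predictive variance", {
  set.seed(33)
  hp <- list(theta1 = 1, theta2 = 2, sigma_n = 0.1)
  for (i in 1:5) {
    X <- matrix(stats::rnorm(16), 8, 2)
    y <- stats::rnorm(8)
    xs <- matrix(stats::rnorm(2), 1, 2)
    v_small <- gpr_predict(gpr_fit(X[1:7, ], y[1:7], hyper = hp), xs)$variance
    v_full <- gpr_predict(gpr_fit(X, y, hyper = hp), xs)$variance
    expect_lte(v_full, v_small + 1e-9)
  }
})

test_that("a smooth 1-d function is recovered below 1e-2 at midpoints", {
  xtr <- seq(0, 2 * pi, length.out = 20)
  m <- gpr_fit(matrix(xtr), sin(xtr), hyper = "optimize", seed = 2)
  xmid <- (xtr[-1] + xtr[-20]) / 2
  p <- gpr_predict(m, matrix(xmid))
  expect_lt(max(abs(p$mean - sin(xmid))), 1e-2)
})

test_that("known hyperparameters are recovered to order of magnitude", {
  set.seed(55)
  n <- 100
  X <- matrix(stats::runif(n, 0, 10))
  th1 <- 4; th2 <- 2; sn <- 0.1
  K <- th1 * exp(-as.matrix(dist(X))^2 / th2) + diag(sn^2, n)
  y <- drop(t(chol(K)) %*% stats::rnorm(n))
  m <- gpr_fit(X, y, hyper = "optimize", seed = 6)
  expect_lt(abs(log10(m$theta1) - log10(th1)), 1.5)
  expect_lt(abs(log10(m$theta2) - log10(th2)), 1.5)
  expect_lt(abs(log10(m$sigma_n) - log10(sn)), 1.5)
})

test_that("duplicate rows with zero noise still factorize via jitter", {
  X <- matrix(c(1, 1, 2), 3, 1)
  y <- c(5, 5, 7)
  m <- gpr_fit(X, y, hyper = list(theta1 = 1, theta2 = 1, sigma_n = 0))
  expect_gt(m$jitter, 0)
  expect_equal(gpr_predict(m, matrix(1))$mean, 5, tolerance = 1e-3)
})

test_that("non-finite inputs are rejected", {
  expect_error(gpr_fit(matrix(c(1, NA)), c(1, 2),
                       hyper = list(theta1 = 1, theta2 = 1, sigma_n = 0)),
               "non-finite")
})
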