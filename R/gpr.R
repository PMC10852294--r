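#' Gaussian kernel
#'
#' The squared-exponential kernel
#' `k(x, x') = theta1 * exp(-||x - x'||^2 / theta2)`: `theta1` is the signal
#' amplitude (prior variance) and `theta2` the squared-length-scale
#' denominator. An alternative multiplicative reading
#' `theta1 * exp(-||x - x'||^2 * theta2)` is available via
#' `theta2_multiplies = TRUE`.
#'
#' @param x,x_prime Equal-length numeric vectors.
#' @param theta1,theta2 Positive kernel hyperparameters.
#' @param theta2_multiplies Use the multiplicative reading (default FALSE).
#' @return Scalar kernel value; symmetric in its arguments.
#' @export
gpr_kernel <- function(x, x_prime, theta1, theta2,
                       theta2_multiplies = FALSE) {
  if (length(x) != length(x_prime)) {
    stop("length mismatch: ", length(x), " vs ", length(x_prime),
         call. = FALSE)
  }
  if (theta1 <= 0 || theta2 <= 0) {
    stop("theta1 and theta2 must be positive", call. = FALSE)
  }
  d2 <- sum((x - x_prime)^2)
  theta1 * exp(if (theta2_multiplies) -d2 * theta2 else -d2 / theta2)
}

# Pairwise squared Euclidean distances between rows of A and rows of B.
sq_dist <- function(A, B = A) {
  A <- as.matrix(A); B <- as.matrix(B)
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  d2
}

# Cholesky of K + sigma_n^2 I with escalating jitter (1e-10..1e-4 of the
# mean kernel diagonal). Returns list(L upper-tri chol, jitter) or errors.
chol_with_jitter <- function(K, sigma_n) {
  n <- nrow(K)
  diag_add <- sigma_n^2
  scale <- sum(diag(K)) / n
  for (j in c(0, 10^seq(-10, -4))) {
    C <- K + diag(diag_add + j * scale, n)
    L <- tryCatch(chol(C), error = function(e) NULL)
    if (!is.null(L)) return(list(L = L, jitter = j * scale))
  }
  stop("fit error: kernel matrix not positive definite after jitter ",
       "escalation", call. = FALSE)
}

#' Fit a Gaussian process regression model
#'
#' Builds the kernel matrix `K` on the training rows, factorizes
#' `K + sigma_n^2 I` by Cholesky (with escalating diagonal jitter if
#' needed; an explicit matrix inverse is never formed) and stores what the
#' predictive equations need. With `hyper = "optimize"` the hyperparameters
#' `(theta1, theta2, sigma_n)` are chosen by maximizing the log marginal
#' likelihood with analytic gradients (L-BFGS-B on the log scale) from
#' `n_starts` multi-starts: a data-driven start (`theta1 = var(y)`,
#' `theta2` = median pairwise squared distance) plus seeded log-scale
#' perturbations of it.
#'
#' @param X Numeric feature matrix (rows = observations).
#' @param y Numeric objective vector.
#' @param hyper Either the string `"optimize"` or a list/vector with
#'   elements `theta1`, `theta2`, `sigma_n`.
#' @param seed Seed for the multi-start perturbations.
#' @param n_starts Number of optimizer starts (default 5).
#' @param theta2_multiplies See [gpr_kernel()].
#' @return An object of class `gpr_model`.
#' @export
gpr_fit <- function(X, y, hyper = "optimize", seed = 1L, n_starts = 5,
                    theta2_multiplies = FALSE) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  if (n < 1L || length(y) != n) {
    stop("need N >= 1 rows and matching y", call. = FALSE)
  }
  if (any(!is.finite(X)) || any(!is.finite(y))) {
    stop("non-finite entries in X or y", call. = FALSE)
  }
  D2 <- sq_dist(X)

  if (identical(hyper, "optimize")) {
    if (theta2_multiplies) {
      stop("optimization supports only the division reading; pass explicit ",
           "hyperparameters for the multiplicative one", call. = FALSE)
    }
    hp <- optimize_hyper(D2, y, seed = seed, n_starts = n_starts)
  } else {
    hp <- as.list(hyper)
    stopifnot(hp$theta1 > 0, hp$theta2 > 0, hp$sigma_n >= 0)
  }
  K <- if (theta2_multiplies) {
    hp$theta1 * exp(-D2 * hp$theta2)
  } else {
    hp$theta1 * exp(-D2 / hp$theta2)
  }
  fac <- chol_with_jitter(K, hp$sigma_n)
  alpha <- backsolve(fac$L, forwardsolve(t(fac$L), y))
  structure(
    list(X = X, y = y,
         theta1 = hp$theta1, theta2 = hp$theta2, sigma_n = hp$sigma_n,
         theta2_multiplies = theta2_multiplies,
         L = fac$L, alpha = alpha, jitter = fac$jitter, n = n),
    class = "gpr_model"
  )
}

# Negative log marginal likelihood and its gradient in
# p = (log theta1, log theta2, log sigma_n), for fixed D2 and y.
nlml_with_grad <- function(p, D2, y) {
  n <- length(y)
  th1 <- exp(p[1]); th2 <- exp(p[2]); sn <- exp(p[3])
  Kf <- th1 * exp(-D2 / th2)
  fac <- tryCatch(chol_with_jitter(Kf, sn), error = function(e) NULL)
  if (is.null(fac)) return(list(value = 1e10, grad = c(0, 0, 0)))
  L <- fac$L
  alpha <- backsolve(L, forwardsolve(t(L), y))
  nll <- 0.5 * sum(y * alpha) + sum(log(diag(L))) + 0.5 * n * log(2 * pi)
  Kinv <- chol2inv(L)
  W <- tcrossprod(alpha) - Kinv           # d logZ / dC = 0.5 * W
  g1 <- 0.5 * sum(W * Kf)                 # dC/dlog th1 = Kf
  g2 <- 0.5 * sum(W * (Kf * D2 / th2))    # dC/dlog th2
  g3 <- 0.5 * sum(diag(W)) * 2 * sn^2     # dC/dlog sn = 2 sn^2 I
  list(value = nll, grad = -c(g1, g2, g3))
}

optimize_hyper <- function(D2, y, seed = 1L, n_starts = 5) {
  n <- length(y)
  off <- D2[upper.tri(D2)]
  med_d2 <- if (length(off) && any(off > 0)) stats::median(off[off > 0]) else 1
  vy <- max(stats::var(y), 1e-8)
  if (n == 1L) vy <- max(y^2, 1)
  base <- c(log(vy), log(med_d2), log(max(0.1 * sqrt(vy), 1e-4)))
  starts <- with_seed(derive_seed(seed, "gpr-starts"), {
    s <- list(base)
    if (n_starts > 1) {
      for (i in seq_len(n_starts - 1)) {
        s <- c(s, list(base + stats::rnorm(3, 0, 2)))
      }
    }
    s
  })
  lower <- c(-15, log(med_d2) - 12, -12)
  upper <- c(25, log(med_d2) + 12, 12)
  best <- NULL
  for (p0 in starts) {
    p0 <- pmin(pmax(p0, lower), upper)
    res <- tryCatch(
      stats::optim(p0,
                   fn = function(p) nlml_with_grad(p, D2, y)$value,
                   gr = function(p) nlml_with_grad(p, D2, y)$grad,
                   method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = 100)),
      error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$value < best$value)) {
      best <- res
    }
  }
  if (is.null(best)) stop("fit error: hyperparameter optimization failed",
                          call. = FALSE)
  list(theta1 = exp(best$par[1]), theta2 = exp(best$par[2]),
       sigma_n = exp(best$par[3]), nlml = best$value)
}

#' Predict from a fitted GPR model
#'
#' Predictive distribution at new points: mean `k*' (K + sigma_n^2 I)^-1 y`
#' and variance `k** - k*' (K + sigma_n^2 I)^-1 k*`, computed via triangular
#' solves against the stored Cholesky factor. Tiny negative variances from
#' round-off (above -1e-9) are clamped to 0; anything more negative warns.
#'
#' @param model A `gpr_model`.
#' @param x_star Numeric vector (one point) or matrix (rows = points) with
#'   the training dimensionality.
#' @return List with numeric vectors `mean` and `variance`, plus `k_star`
#'   (matrix of train-vs-test kernel values) and `k_starstar`.
#' @export
gpr_predict <- function(model, x_star) {
  stopifnot(inherits(model, "gpr_model"))
  Xs <- if (is.matrix(x_star)) x_star else matrix(x_star, nrow = 1)
  if (ncol(Xs) != ncol(model$X)) {
    stop("dimension mismatch: expected ", ncol(model$X), " features, got ",
         ncol(Xs), call. = FALSE)
  }
  D2s <- sq_dist(model$X, Xs)
  Ks <- if (isTRUE(model$theta2_multiplies)) {
    model$theta1 * exp(-D2s * model$theta2)
  } else {
    model$theta1 * exp(-D2s / model$theta2)                       # n x m
  }
  mean <- drop(crossprod(Ks, model$alpha))
  V <- forwardsolve(t(model$L), Ks)
  variance <- model$theta1 - colSums(V^2)
  neg <- variance < 0
  if (any(variance < -1e-9)) {
    warning("predictive variance clamped from ", min(variance), " to 0")
  }
  variance[neg] <- 0
  list(mean = mean, variance = variance, k_star = Ks,
       k_starstar = model$theta1)
}

#' Log marginal likelihood of a fitted GPR model
#'
#' `-1/2 y' (K + sigma_n^2 I)^-1 y - 1/2 log det(K + sigma_n^2 I)
#'  - N/2 log(2 pi)`, evaluated from the stored Cholesky factorization.
#'
#' @param model A `gpr_model`.
#' @return Scalar log marginal likelihood.
#' @export
gpr_log_marginal <- function(model) {
  if (!inherits(model, "gpr_model") || is.null(model$L)) {
    stop("unfitted model", call. = FALSE)
  }
  -0.5 * sum(model$y * model$alpha) - sum(log(diag(model$L))) -
    0.5 * model$n * log(2 * pi)
}

#' @export
print.gpr_model <- function(x, ...) {
  cat(sprintf(
    "<gpr_model> N=%d d=%d  theta1=%.4g theta2=%.4g sigma_n=%.4g  logML=%.3f\n",
    x$n, ncol(x$X), x$theta1, x$theta2, x$sigma_n, gpr_log_marginal(x)))
  invisible(x)
}
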