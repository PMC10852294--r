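# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

#' Derive a stage-specific seed from a global seed
#'
#' Every randomized stage of the pipeline draws its seed deterministically
#' from the global seed and a stage label, so a single `--seed` reproduces the
#' whole run while stages stay statistically decoupled.
#'
#' @param seed Integer global seed.
#' @param stage Character stage label (e.g. `"simulate"`, `"sensory"`).
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- as.double(seed) %% 2147483647
  for (ch in utf8ToInt(paste(stage, collapse = ""))) {
    h <- (h * 131 + ch) %% 2147483647
  }
  as.integer(h)
}

# Trapezoidal integral of y over x (non-uniform grids allowed).
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

# Centered moving average with window of `n` samples (n >= 1). Edges use the
# partial window so the output has the same length and no NA padding.
moving_average <- function(x, n) {
  n <- max(1L, as.integer(n))
  if (n == 1L) return(x)
  cs <- cumsum(c(0, x))
  half <- n %/% 2L
  i <- seq_along(x)
  lo <- pmax(i - half, 1L)
  hi <- pmin(i + (n - 1L - half), length(x))
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Sample moments on a numeric vector: Fisher skewness g1 = m3/m2^1.5 and
# non-excess kurtosis m4/m2^2. Degenerate (zero-variance) input returns 0s.
sample_moments <- function(x) {
  m <- mean(x)
  d <- x - m
  m2 <- mean(d^2)
  if (m2 <= 0) {
    return(list(mean = m, sd = 0, variance = 0, skewness = 0, kurtosis = 0))
  }
  list(
    mean = m,
    sd = stats::sd(x),
    variance = stats::var(x),
    skewness = mean(d^3) / m2^1.5,
    kurtosis = mean(d^4) / m2^2
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
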