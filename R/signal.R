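# Noise gating, peak detection and spectral band averaging shared by the
# vibration and sound feature extractors.

#' Estimate amplifier-noise sigma from a pre-motion baseline
#'
#' The stationary amplifier noise SD is estimated as the sample SD of the
#' mean-removed baseline window recorded before the probe moves.
#'
#' @param signal Numeric series.
#' @param baseline_idx Integer indices of the baseline window.
#' @param motion_start Optional index of motion onset; a baseline overlapping
#'   it is permitted but flagged with a warning.
#' @return Estimated noise SD (0 for a constant baseline).
#' @export
estimate_noise_sigma <- function(signal, baseline_idx,
                                 motion_start = NULL) {
  if (length(baseline_idx) == 0L) {
    stop("empty baseline window", call. = FALSE)
  }
  if (!is.null(motion_start) && max(baseline_idx) >= motion_start) {
    warning("baseline window overlaps motion onset; sigma may be inflated")
  }
  x <- signal[baseline_idx]
  if (length(x) < 2L) return(0)
  stats::sd(x - mean(x))
}

#' Three-sigma noise gate
#'
#' Zeroes every sample whose magnitude does not exceed `k` times the noise
#' SD; surviving samples pass unchanged. With `sigma = 0` the gate is the
#' identity on nonzero samples. The gate is idempotent.
#'
#' @param signal Numeric series (baseline-zeroed, i.e. mean already removed).
#' @param sigma Noise SD (>= 0).
#' @param k Gate multiple (study uses 3).
#' @return Gated series.
#' @export
noise_gate <- function(signal, sigma, k = 3) {
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  out <- signal
  out[abs(out) <= k * sigma] <- 0
  out
}

# Local maxima of x (strictly positive height) with a minimum separation in
# samples, selected greedily by descending height. Returns sorted indices.
find_signal_peaks <- function(x, min_sep) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  cand <- which(x[2:(n - 1L)] > x[1:(n - 2L)] &
                  x[2:(n - 1L)] >= x[3:n] &
                  x[2:(n - 1L)] > 0) + 1L
  if (length(cand) == 0L) return(integer(0))
  cand <- cand[order(x[cand], decreasing = TRUE)]
  taken <- integer(0)
  for (i in cand) {
    if (length(taken) == 0L || all(abs(taken - i) >= min_sep)) {
      taken <- c(taken, i)
    }
  }
  sort(taken)
}

# One-sided magnitude spectrum of x at rate fs: list(freq, mag) excluding DC.
# Records whose length is not highly composite are zero-padded to the next
# 2-3-5-smooth length for the FFT; magnitudes stay normalized by the true
# record length.
magnitude_spectrum <- function(x, fs) {
  n <- length(x)
  if (n == 0L) stop("empty signal", call. = FALSE)
  N <- stats::nextn(n, c(2L, 3L, 5L))
  if (N > n) x <- c(x, numeric(N - n))
  sp <- stats::fft(x)
  half <- floor(N / 2)
  idx <- seq_len(half) + 1L              # drop DC bin
  list(freq = (idx - 1L) * fs / N, mag = Mod(sp[idx]) / n)
}

# Mean spectral magnitude over bins with freq in [fc*lo_mult, fc*hi_mult) per
# center. Bands with no bins (above Nyquist or below resolution) return 0
# with a warning.
band_means <- function(freq, mag, centers, lo_mult, hi_mult) {
  vapply(centers, function(fc) {
    sel <- freq >= fc * lo_mult & freq < fc * hi_mult
    if (!any(sel)) {
      warning(sprintf("band centered at %g Hz has no spectral bins", fc))
      return(0)
    }
    mean(mag[sel])
  }, numeric(1))
}
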