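#' Octave-band table for the vibration channel
#'
#' Twelve octave bands with nominal centers 1-2000 Hz. Exact centers are the
#' base-2 series 2^0 .. 2^11 Hz; nominal labels follow the conventional
#' renaming of 32 and 64 Hz to 31.5 and 63 Hz. Band edges are
#' `fc * 2^(+/-1/2)` on the exact centers.
#'
#' @return data.frame with columns `nominal` and `exact` (Hz), 12 rows.
#' @export
octave_band_centers <- function() {
  data.frame(
    nominal = c(1, 2, 4, 8, 16, 31.5, 63, 125, 250, 500, 1000, 2000),
    exact = 2^(0:11)
  )
}

# Fixed 22-column schema of the vibration block.
vibration_feature_names <- function() {
  c("vib_ma_peak_max_c1_V", "vib_ma_peak_max_c2_V", "vib_overall_max_V",
    "vib_n_peaks", "vib_mean_peak_interval_s",
    "vib_mean_V", "vib_sd_V", "vib_variance_V2",
    "vib_skewness", "vib_kurtosis",
    paste0("vib_oct_", sub("\\.", "p", octave_band_centers()$nominal), "Hz"))
}

#' Extract the 22 vibration features from a chew recording
#'
#' Pipeline: zero the baseline (subtract the pre-motion mean), estimate the
#' amplifier-noise SD from the pre-motion window, gate at `k_sigma` times
#' that SD, rectify (absolute value), then compute
#' * the maxima, over each compression cycle, of the moving average
#'   (`ma_window_s`, default 10 ms) of the rectified series;
#' * the overall maximum of the rectified series (the block's 10th
#'   time-series value, configurable off via `include_overall_max`, in which
#'   case the column is emitted as 0);
#' * the number of peaks (local maxima of the rectified gated series with
#'   minimum separation `peak_min_sep_s`, default 5 ms) and the mean
#'   interval between successive peaks (0 when fewer than 2 peaks);
#' * mean, SD, variance, Fisher skewness and (non-excess) kurtosis of the
#'   rectified gated series;
#' * twelve octave-band means of the magnitude spectrum of the full gated
#'   record ([octave_band_centers()]).
#'
#' @param recording A `chew_recording`.
#' @param k_sigma Noise-gate multiple (default 3).
#' @param ma_window_s Moving-average window (s).
#' @param peak_min_sep_s Minimum peak separation (s).
#' @param include_overall_max Emit the overall rectified maximum as the 10th
#'   time-series feature (default TRUE).
#' @param cycle_bounds Optional precomputed cycle bounds (force-channel
#'   indices); defaults to [segment_cycles()] on the actuation.
#' @return Named numeric vector of length 22 in the fixed schema order.
#' @export
extract_vibration_features <- function(recording, k_sigma = 3,
                                       ma_window_s = 0.010,
                                       peak_min_sep_s = 0.005,
                                       include_overall_max = TRUE,
                                       cycle_bounds = NULL) {
  stopifnot(inherits(recording, "chew_recording"))
  fs <- recording$force_fs_Hz
  x <- recording$vibration
  if (length(x) == 0L) stop("empty recording", call. = FALSE)
  if (is.null(cycle_bounds)) {
    cycle_bounds <- segment_cycles(recording$force, recording$actuation)
  }
  base_idx <- seq_len(min(recording$baseline_n, length(x)))
  feats <- peak_train_features(
    x, fs, base_idx, cycle_bounds, k_sigma, ma_window_s, peak_min_sep_s,
    include_overall_max = include_overall_max)
  bands <- octave_band_centers()
  sp <- magnitude_spectrum(feats$gated, fs)
  oct_means <- band_means(sp$freq, sp$mag, bands$exact, 2^(-1 / 2), 2^(1 / 2))
  out <- c(feats$stats, oct_means)
  stats::setNames(out, vibration_feature_names())
}

# Shared time-series pipeline for vibration and sound: baseline zeroing,
# sigma estimation, gating, rectification, moving-average cycle maxima, peak
# train statistics and sample moments. `cycle_bounds` are indices on the
# force-channel grid; they are rescaled to this channel's rate.
peak_train_features <- function(x, fs, baseline_idx, cycle_bounds,
                                k_sigma, ma_window_s, peak_min_sep_s,
                                include_overall_max = TRUE,
                                bounds_fs = fs) {
  x0 <- x - mean(x[baseline_idx])
  sigma <- estimate_noise_sigma(x0, baseline_idx)
  g <- noise_gate(x0, sigma, k = k_sigma)
  g[baseline_idx] <- 0                      # baseline is noise by definition
  r <- abs(g)
  ma <- moving_average(r, round(ma_window_s * fs))
  scale_i <- fs / bounds_fs
  cyc_max <- vapply(cycle_bounds, function(b) {
    lo <- max(1L, ceiling(b[1] * scale_i))
    hi <- min(length(r), floor(b[2] * scale_i))
    if (lo > hi) 0 else max(ma[lo:hi])
  }, numeric(1))
  peaks <- find_signal_peaks(r, max(1L, round(peak_min_sep_s * fs)))
  n_peaks <- length(peaks)
  mean_int <- if (n_peaks >= 2L) mean(diff(peaks)) / fs else 0
  mom <- sample_moments(r)
  list(
    stats = c(cyc_max[1], cyc_max[2],
              if (include_overall_max) max(r) else 0,
              n_peaks, mean_int,
              mom$mean, mom$sd, mom$variance, mom$skewness, mom$kurtosis),
    gated = g, rectified = r, sigma = sigma, peaks = peaks
  )
}
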