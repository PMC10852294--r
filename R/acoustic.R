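#' A-weighting gain
#'
#' Standard A-weighting frequency response (IEC 61672 closed form),
#' normalized to exactly 0 dB at 1 kHz.
#'
#' @param frequency_Hz Frequency in Hz (vectorized, must be > 0).
#' @return Gain in dB.
#' @export
a_weight <- function(frequency_Hz) {
  if (any(frequency_Hz <= 0)) {
    stop("frequency must be positive", call. = FALSE)
  }
  ra <- function(f) {
    f2 <- f^2
    (12194^2 * f2^2) /
      ((f2 + 20.6^2) * sqrt((f2 + 107.7^2) * (f2 + 737.9^2)) * (f2 + 12194^2))
  }
  20 * log10(ra(frequency_Hz)) - 20 * log10(ra(1000))
}

#' One-third-octave band table for the sound channel
#'
#' The 23 one-third-octave bands with nominal centers 80-12500 Hz. Exact
#' centers are the base-2 series `1000 * 2^(k/3)` for k = -11..11; band
#' edges are `fc * 2^(+/-1/6)` on the exact centers.
#'
#' @return data.frame with columns `nominal` and `exact` (Hz), 23 rows.
#' @export
third_octave_centers <- function() {
  data.frame(
    nominal = c(80, 100, 125, 160, 200, 250, 315, 400, 500, 630, 800,
                1000, 1250, 1600, 2000, 2500, 3150, 4000, 5000, 6300,
                8000, 10000, 12500),
    exact = 1000 * 2^((-11:11) / 3)
  )
}

#' A-weighted one-third-octave band means
#'
#' Magnitude spectrum of the signal with the A-weighting applied per bin
#' (linear gain), averaged over the bins of each of the 23 one-third-octave
#' bands ([third_octave_centers()]). Bands whose upper edge exceeds the
#' Nyquist frequency are returned as 0 with a warning.
#'
#' @param sound Numeric sound-pressure series (Pa).
#' @param fs Sampling rate (Hz).
#' @return Numeric vector of 23 band means, ascending center frequency.
#' @export
third_octave_band_means <- function(sound, fs) {
  if (length(sound) == 0L) stop("empty signal", call. = FALSE)
  bands <- third_octave_centers()
  sp <- magnitude_spectrum(sound, fs)
  mag_a <- sp$mag * 10^(a_weight(sp$freq) / 20)
  out <- numeric(nrow(bands))
  ok <- bands$exact * 2^(1 / 6) <= fs / 2
  if (!all(ok)) {
    warning(sum(!ok), " one-third-octave band(s) above Nyquist set to 0")
  }
  out[ok] <- band_means(sp$freq, mag_a, bands$exact[ok],
                        2^(-1 / 6), 2^(1 / 6))
  out
}

# Critical-band (Bark) rate of a frequency in Hz.
bark_rate <- function(f) {
  13 * atan(0.00076 * f) + 3.5 * atan((f / 7500)^2)
}

#' Frame-wise loudness and sharpness (band-level Zwicker-style approximation)
#'
#' Stationary loudness and sharpness computed per non-overlapping frame from
#' one-third-octave band levels. Per frame, each band's sound pressure level
#' is converted to a specific loudness via the 1-sone-at-40-phon power law
#' `N'_k = 2^((L_k - 40) / 10)` (bands below `floor_dB` contribute 0), and
#' total loudness is the specific loudness integrated over the critical-band
#' (Bark) widths of the bands. Sharpness is the weighted first moment of
#' specific loudness over critical-band rate,
#' `S = c * sum(N'_k g(z_k) z_k dz_k) / sum(N'_k dz_k)` with the standard
#' high-frequency emphasis `g(z) = 1` below 15.8 Bark rising exponentially
#' above, and is defined as 0 when total loudness is 0. This is a documented
#' approximation of the full psychoacoustic standard: it omits spectral
#' masking spread and the exact threshold-in-quiet contour, which is
#' acceptable here because the values feed a learned regressor rather than
#' absolute psychoacoustic reporting.
#'
#' @param sound Calibrated sound-pressure series (Pa).
#' @param fs Sampling rate (Hz).
#' @param frame_s Frame length in seconds (default 0.05, non-overlapping).
#' @param floor_dB Band SPL below which a band contributes no loudness
#'   (default 0 dB SPL).
#' @return List with numeric vectors `loudness_sone` and `sharpness_acum`,
#'   one value per frame.
#' @export
loudness_sharpness <- function(sound, fs, frame_s = 0.05, floor_dB = 0) {
  n <- length(sound)
  if (n == 0L) stop("empty signal", call. = FALSE)
  flen <- round(frame_s * fs)
  if (flen > n) {
    warning("frame longer than signal; using a single frame")
    flen <- n
  }
  nfr <- n %/% flen
  bands <- third_octave_centers()
  lo <- bands$exact * 2^(-1 / 6)
  hi <- pmin(bands$exact * 2^(1 / 6), fs / 2)
  z <- bark_rate(bands$exact)
  dz <- pmax(bark_rate(hi) - bark_rate(pmin(lo, hi)), 0)
  gz <- ifelse(z <= 15.8, 1, 0.15 * exp(0.42 * (z - 15.8)) + 0.85)
  p0sq <- (2e-5)^2
  loud <- sharp <- numeric(nfr)
  for (j in seq_len(nfr)) {
    x <- sound[((j - 1L) * flen + 1L):(j * flen)]
    sp <- stats::fft(x)
    m <- length(x)
    pw <- Mod(sp)^2 / m^2                 # per-bin power, two-sided
    freq <- (seq_len(m) - 1L) * fs / m
    half <- 2:(floor(m / 2) + 1L)         # one-sided, DC dropped
    pband <- vapply(seq_len(nrow(bands)), function(k) {
      sel <- half[freq[half] >= lo[k] & freq[half] < hi[k]]
      2 * sum(pw[sel])
    }, numeric(1))
    L <- ifelse(pband > 0, 10 * log10(pband / p0sq), -Inf)
    nprime <- ifelse(L >= floor_dB, 2^((L - 40) / 10), 0)
    tot <- sum(nprime * dz)
    loud[j] <- tot
    sharp[j] <- if (tot > 0) 0.11 * sum(nprime * gz * z * dz) / tot else 0
  }
  list(loudness_sone = loud, sharpness_acum = sharp)
}

# Fixed 38-column schema of the sound block.
sound_feature_names <- function() {
  c("snd_ma_peak_max_c1_Pa", "snd_ma_peak_max_c2_Pa",
    "snd_n_peaks", "snd_mean_peak_interval_s",
    "snd_max_Pa", "snd_mean_Pa", "snd_sd_Pa", "snd_variance_Pa2",
    "snd_skewness", "snd_kurtosis",
    "snd_loudness_max_sone", "snd_loudness_mean_sone",
    "snd_sharpness_max_acum", "snd_sharpness_mean_acum",
    "snd_aweighted_level_dBA",
    paste0("snd_toct_", third_octave_centers()$nominal, "Hz"))
}

#' Extract the 38 sound features from a chew recording
#'
#' The sound channel is cleaned exactly as the vibration channel (baseline
#' zeroing, noise sigma from the sound channel's own pre-motion baseline,
#' 3-sigma gate, rectification), then the block's 38 values are computed:
#' ten time-series statistics (cycle-wise moving-average peak maxima, peak
#' count and mean peak interval, overall maximum, mean, SD, variance,
#' skewness, kurtosis), loudness and sharpness maxima and means over 50-ms
#' frames ([loudness_sharpness()], computed on the gated signal), the
#' overall A-weighted level in dBA (reported as 0 for an all-zero record),
#' and 23 A-weighted one-third-octave band means
#' ([third_octave_band_means()]).
#'
#' @param recording A `chew_recording`.
#' @param k_sigma,ma_window_s,peak_min_sep_s As in
#'   [extract_vibration_features()].
#' @param frame_s Loudness/sharpness frame length (s).
#' @param include_dBA Emit the overall A-weighted level as the 38th feature
#'   (default TRUE; 0 when disabled).
#' @param cycle_bounds Optional precomputed cycle bounds on the force grid.
#' @return Named numeric vector of length 38 in the fixed schema order.
#' @export
extract_sound_features <- function(recording, k_sigma = 3,
                                   ma_window_s = 0.010,
                                   peak_min_sep_s = 0.005,
                                   frame_s = 0.05,
                                   include_dBA = TRUE,
                                   cycle_bounds = NULL) {
  stopifnot(inherits(recording, "chew_recording"))
  fs <- recording$sound_fs_Hz
  x <- recording$sound
  if (length(x) == 0L) stop("empty recording", call. = FALSE)
  if (is.null(cycle_bounds)) {
    cycle_bounds <- segment_cycles(recording$force, recording$actuation)
  }
  base_idx <- seq_len(min(recording$baseline_n_sound, length(x)))
  feats <- peak_train_features(
    x, fs, base_idx, cycle_bounds, k_sigma, ma_window_s, peak_min_sep_s,
    include_overall_max = TRUE, bounds_fs = recording$force_fs_Hz)
  # reorder: vibration-style (ma1, ma2, max, n, int, moments) ->
  # sound schema (ma1, ma2, n, int, max, moments)
  ts <- feats$stats[c(1, 2, 4, 5, 3, 6, 7, 8, 9, 10)]

  ls <- loudness_sharpness(feats$gated, fs, frame_s = frame_s)
  dBA <- 0
  if (include_dBA && any(feats$gated != 0)) {
    sp <- magnitude_spectrum(feats$gated, fs)
    pw <- 2 * sum((sp$mag * 10^(a_weight(sp$freq) / 20))^2)
    if (pw > 0) dBA <- 10 * log10(pw / (2e-5)^2)
  }
  toct <- third_octave_band_means(feats$gated, fs)
  out <- c(ts,
           max(ls$loudness_sone), mean(ls$loudness_sone),
           max(ls$sharpness_acum), mean(ls$sharpness_acum),
           dBA, toct)
  stats::setNames(out, sound_feature_names())
}
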