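#' Texture descriptors used throughout the package
#'
#' The four Japanese onomatopoeic crispness/crunchiness descriptors rated by
#' the sensory panel: *sakusaku* (easily broken with weak force), *karikari*
#' (short hard fracture), *paripari* (thin food, high-frequency sound) and
#' *zakuzaku* (layered fracture, low-frequency sound).
#'
#' @export
TEXTURES <- c("sakusaku", "karikari", "paripari", "zakuzaku")

#' Sensory conditions
#'
#' Condition 1: normal chewing (force + bone-conduction sound + air-conduction
#' sound). Condition 2: air-conduction sound blocked. Condition 3: air-
#' conduction sound only (playback).
#'
#' @export
CONDITIONS <- 1:3

#' Define a snack-sample archetype for the chew simulator
#'
#' An archetype bundles the mechanical and acoustic parameters that control
#' how one snack food behaves under the instrumented two-compression test,
#' together with its latent ("true") texture intensities on the 0-120 line
#' scale.
#'
#' @param sample_id Label, e.g. `"S1"`.
#' @param height_mm Sample height in mm (probe travel is a fraction of this).
#' @param peak_force_N Force scale of the first compression (N).
#' @param brittleness Fraction of force lost at the major fracture, in `[0,1]`.
#' @param fracture_event_rate Expected fracture events per second during
#'   probe descent.
#' @param second_bite_event_ratio Expected second-compression event count as a
#'   fraction of the first-compression count, in `[0,1]` (crisp foods shatter
#'   on the first bite, so the second bite is quieter).
#' @param vibration_spike_amp_V Peak amplitude of a fracture burst on the
#'   probe-vibration channel (V).
#' @param sound_spike_amp_Pa Peak amplitude of a fracture burst on the
#'   microphone channel (Pa).
#' @param adhesive_force_N Magnitude of the negative (tensile) force tail
#'   after the first compression (N); 0 for non-sticky foods.
#' @param true_texture_intensity Named numeric vector over
#'   [TEXTURES] with latent intensities in `[0,120]`.
#' @param vib_carrier_Hz,sound_carrier_Hz Carrier frequency of the decaying-
#'   sinusoid fracture bursts on each channel; distinct carriers give
#'   archetypes distinct octave-band signatures.
#' @return An object of class `sample_archetype`.
#' @export
sample_archetype <- function(sample_id,
                             height_mm,
                             peak_force_N,
                             brittleness = 0.5,
                             fracture_event_rate = 50,
                             second_bite_event_ratio = 0.2,
                             vibration_spike_amp_V = 0.5,
                             sound_spike_amp_Pa = 0.2,
                             adhesive_force_N = 0,
                             true_texture_intensity = stats::setNames(
                               rep(60, 4), TEXTURES),
                             vib_carrier_Hz = 800,
                             sound_carrier_Hz = 3000) {
  if (!is.numeric(height_mm) || height_mm <= 0) {
    stop("invalid-config: height_mm must be > 0", call. = FALSE)
  }
  if (peak_force_N <= 0) {
    stop("invalid-config: peak_force_N must be > 0", call. = FALSE)
  }
  if (brittleness < 0 || brittleness > 1) {
    stop("invalid-config: brittleness must be in [0,1]", call. = FALSE)
  }
  if (fracture_event_rate < 0) {
    stop("invalid-config: fracture_event_rate must be >= 0", call. = FALSE)
  }
  if (second_bite_event_ratio < 0 || second_bite_event_ratio > 1) {
    stop("invalid-config: second_bite_event_ratio must be in [0,1]",
         call. = FALSE)
  }
  if (adhesive_force_N < 0) {
    stop("invalid-config: adhesive_force_N must be >= 0", call. = FALSE)
  }
  tti <- true_texture_intensity[TEXTURES]
  if (anyNA(tti) || any(tti < 0 | tti > 120)) {
    stop("invalid-config: true_texture_intensity must cover all four ",
         "textures with values in [0,120]", call. = FALSE)
  }
  structure(
    list(
      sample_id = as.character(sample_id),
      height_mm = height_mm,
      peak_force_N = peak_force_N,
      brittleness = brittleness,
      fracture_event_rate = fracture_event_rate,
      second_bite_event_ratio = second_bite_event_ratio,
      vibration_spike_amp_V = vibration_spike_amp_V,
      sound_spike_amp_Pa = sound_spike_amp_Pa,
      adhesive_force_N = adhesive_force_N,
      true_texture_intensity = tti,
      vib_carrier_Hz = vib_carrier_Hz,
      sound_carrier_Hz = sound_carrier_Hz
    ),
    class = "sample_archetype"
  )
}

#' Default eight snack archetypes
#'
#' Eight archetypes (S1-S8) emulating the study foods: sable, thin rice
#' cracker, ellipsoid rice cracker, potato chip, pretzel stick, biscuit,
#' fried sweet-potato stick and cubic rice cracker. Heights are the study's
#' measured sample heights; the remaining mechanical/acoustic parameters and
#' latent texture intensities are simulator assumptions chosen to reproduce
#' the qualitative contrasts between the foods (thin crackers and chips are
#' loud and paripari-dominant, pretzel and sweet-potato sticks karikari-
#' dominant, the biscuit and cubic cracker hard and zakuzaku-dominant).
#'
#' @return A named list of eight [sample_archetype] objects.
#' @export
default_archetypes <- function() {
  heights <- c(S1 = 6.2, S2 = 5.1, S3 = 8.3, S4 = 4.3,
               S5 = 3.4, S6 = 12.5, S7 = 5.1, S8 = 17.9)
  ints <- function(s, k, p, z) {
    stats::setNames(c(s, k, p, z), TEXTURES)
  }
  params <- list(
    #        peakN  brit rate ratio vibV soundPa adh  vibHz sndHz intensities
    S1 = list(15, 0.50,  55, 0.20, 0.60, 0.10, 0.3,  500, 2000, ints(80, 30, 25, 40)),
    S2 = list(10, 0.40, 120, 0.15, 0.45, 0.35, 0.0,  900, 5000, ints(55, 35, 90, 25)),
    S3 = list(18, 0.50,  60, 0.20, 0.70, 0.12, 0.2,  600, 2500, ints(75, 40, 35, 45)),
    S4 = list( 6, 0.60, 100, 0.10, 0.30, 0.30, 0.0, 1100, 6500, ints(60, 25, 95, 15)),
    S5 = list(25, 0.70,  60, 0.15, 0.90, 0.25, 0.0,  800, 4000, ints(40, 85, 45, 30)),
    S6 = list(30, 0.35,  40, 0.30, 0.80, 0.15, 0.4,  400, 1500, ints(65, 30, 20, 70)),
    S7 = list(35, 0.70,  35, 0.20, 1.20, 0.28, 0.0,  700, 3500, ints(25, 90, 20, 45)),
    S8 = list(45, 0.45,  70, 0.25, 1.40, 0.45, 0.0,  300, 1200, ints(35, 50, 20, 85))
  )
  out <- lapply(names(params), function(id) {
    s <- params[[id]]
    sample_archetype(
      sample_id = id,
      height_mm = heights[[id]],
      peak_force_N = s[[1]],
      brittleness = s[[2]],
      fracture_event_rate = s[[3]],
      second_bite_event_ratio = s[[4]],
      vibration_spike_amp_V = s[[5]],
      sound_spike_amp_Pa = s[[6]],
      adhesive_force_N = s[[7]],
      vib_carrier_Hz = s[[8]],
      sound_carrier_Hz = s[[9]],
      true_texture_intensity = s[[10]]
    )
  })
  stats::setNames(out, names(params))
}

#' Chew-simulator configuration
#'
#' Acquisition and actuation parameters of the instrumented two-chew test:
#' the probe compresses the sample at `probe_speed_mm_s` down to
#' `travel_fraction` of its height, returns, and repeats, while force and
#' probe vibration are sampled at `force_fs_Hz` and sound at `sound_fs_Hz`.
#' A pre-motion baseline of pure amplifier noise is recorded first; the
#' downstream noise gate estimates its standard deviation from that window.
#'
#' @param force_fs_Hz Sampling rate of force and vibration (Hz).
#' @param sound_fs_Hz Sampling rate of the microphone (Hz).
#' @param probe_speed_mm_s Probe velocity (mm/s).
#' @param travel_fraction Fraction of sample height travelled, in `(0,1]`.
#' @param n_compressions Number of compression cycles (the study uses 2).
#' @param vib_noise_sd_V,sound_noise_sd_Pa Stationary amplifier-noise SDs.
#' @param baseline_s Pre-motion baseline duration (s); must be >= 0.2 so the
#'   noise-sigma estimate is stable.
#' @param pause_s Dwell between compression cycles (s).
#' @param tail_s Post-motion tail (s).
#' @return An object of class `chew_sim_config`.
#' @export
chew_sim_config <- function(force_fs_Hz = 10000,
                            sound_fs_Hz = 51200,
                            probe_speed_mm_s = 10,
                            travel_fraction = 0.8,
                            n_compressions = 2,
                            vib_noise_sd_V = 0.005,
                            sound_noise_sd_Pa = 0.002,
                            baseline_s = 0.3,
                            pause_s = 0.2,
                            tail_s = 0.1) {
  if (force_fs_Hz <= 0 || sound_fs_Hz <= 0) {
    stop("invalid-config: sampling rates must be positive", call. = FALSE)
  }
  if (probe_speed_mm_s <= 0) {
    stop("invalid-config: probe_speed_mm_s must be positive", call. = FALSE)
  }
  if (travel_fraction <= 0 || travel_fraction > 1) {
    stop("invalid-config: travel_fraction must be in (0,1]", call. = FALSE)
  }
  if (n_compressions < 1) {
    stop("invalid-config: n_compressions must be >= 1", call. = FALSE)
  }
  if (vib_noise_sd_V < 0 || sound_noise_sd_Pa < 0) {
    stop("invalid-config: noise SDs must be >= 0", call. = FALSE)
  }
  if (baseline_s < 0.2) {
    stop("invalid-config: baseline_s must be >= 0.2", call. = FALSE)
  }
  structure(
    list(
      force_fs_Hz = force_fs_Hz, sound_fs_Hz = sound_fs_Hz,
      probe_speed_mm_s = probe_speed_mm_s,
      travel_fraction = travel_fraction,
      n_compressions = as.integer(n_compressions),
      vib_noise_sd_V = vib_noise_sd_V,
      sound_noise_sd_Pa = sound_noise_sd_Pa,
      baseline_s = baseline_s, pause_s = pause_s, tail_s = tail_s
    ),
    class = "chew_sim_config"
  )
}

#' Default additive condition effects on the latent texture intensities
#'
#' Shift applied to a texture's latent intensity under each sensory
#' condition (condition 1, normal chewing, is the zero reference). Removing
#' air-conduction sound (condition 2) mildly lowers all four textures, most
#' for the sound-driven karikari and paripari; hearing only the air sound
#' (condition 3) lowers the force/vibration-driven sakusaku and zakuzaku and
#' raises karikari and paripari by the study's reported condition-1 vs
#' condition-3 mean differences of 11.8 and 19.0 scale units.
#'
#' @return A 4 x 3 numeric matrix, rows [TEXTURES], columns conditions 1-3.
#' @export
default_condition_effects <- function() {
  m <- rbind(
    sakusaku = c(0, -3.0, -15.0),
    karikari = c(0, -6.0,  11.8),
    paripari = c(0, -7.0,  19.0),
    zakuzaku = c(0, -2.0, -12.0)
  )
  colnames(m) <- paste0("condition", 1:3)
  m
}
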