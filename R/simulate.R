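#' Simulate one instrumented two-compression chew recording
#'
#' Renders the three channels of one trial of the instrumented chew test: a
#' two-hump compression force curve with fracture events, a probe-vibration
#' channel and a microphone (air-conduction sound) channel carrying
#' fracture-burst spike trains plus stationary Gaussian amplifier noise, and
#' the probe actuation (penetration depth) timeline. Fracture events occur as
#' a Poisson process during probe descent; second-compression events are a
#' binomial thinning of the first-compression events with probability
#' `second_bite_event_ratio`, emulating the near-silence of the second bite
#' of an already-shattered crisp food. Each event emits one exponentially
#' decaying sinusoid burst on the vibration channel and one on the sound
#' channel (hard-truncated at 4 ms), and a brief transient dip in the force
#' curve; the major fracture (controlled by `brittleness`) permanently drops
#' the force. The recording starts with `cfg$baseline_s` seconds of pure
#' amplifier noise used downstream for noise-sigma estimation.
#'
#' @param archetype A [sample_archetype].
#' @param cfg A [chew_sim_config].
#' @param seed Integer seed; identical inputs and seed give bit-identical
#'   recordings.
#' @param condition Sensory condition tag (1, 2 or 3); metadata only, the
#'   physical channels are always rendered and masking happens at the
#'   feature level.
#' @param replicate Replicate index (metadata).
#' @return An object of class `chew_recording`: list with `force`,
#'   `vibration` (V, at `force_fs_Hz`), `sound` (Pa, at `sound_fs_Hz`),
#'   `actuation` (probe depth, mm, at `force_fs_Hz`), sampling rates,
#'   `baseline_n` / `baseline_n_sound` (pure-noise baseline lengths), the
#'   ground-truth `events` log (`time_s`, `cycle`, `vib_amp_V`,
#'   `sound_amp_Pa`, `major`), and metadata.
#' @export
simulate_recording <- function(archetype, cfg = chew_sim_config(),
                               seed = 1L, condition = 1L, replicate = 1L) {
  stopifnot(inherits(archetype, "sample_archetype"),
            inherits(cfg, "chew_sim_config"))
  if (!condition %in% 1:3) {
    stop("invalid-config: condition must be 1, 2 or 3", call. = FALSE)
  }
  with_seed(seed, {
    fs <- cfg$force_fs_Hz
    sfs <- cfg$sound_fs_Hz
    travel <- cfg$travel_fraction * archetype$height_mm
    t_desc <- travel / cfg$probe_speed_mm_s
    if (t_desc <= 0) stop("invalid-config: non-positive descent duration",
                          call. = FALSE)
    nb <- round(cfg$baseline_s * fs)
    nd <- round(t_desc * fs)
    np <- round(cfg$pause_s * fs)
    nt <- round(cfg$tail_s * fs)
    if (nd < 2L) stop("invalid-config: descent shorter than two samples",
                      call. = FALSE)
    ncyc <- cfg$n_compressions

    # actuation: baseline | (descent ascent [pause])*ncyc | tail
    depth_desc <- seq(0, travel, length.out = nd)
    segs <- list(rep(0, nb))
    seg_kind <- "baseline"
    for (k in seq_len(ncyc)) {
      segs <- c(segs, list(depth_desc, rev(depth_desc)))
      seg_kind <- c(seg_kind, paste0(c("desc", "asc"), k))
      if (k < ncyc) {
        segs <- c(segs, list(rep(0, np)))
        seg_kind <- c(seg_kind, paste0("pause", k))
      }
    }
    segs <- c(segs, list(rep(0, nt)))
    seg_kind <- c(seg_kind, "tail")
    seg_len <- vapply(segs, length, integer(1))
    seg_start <- cumsum(c(0L, seg_len[-length(seg_len)]))  # 0-based offsets
    names(seg_start) <- seg_kind
    actuation <- unlist(segs, use.names = FALSE)
    n <- length(actuation)
    time_s <- (seq_len(n) - 1L) / fs
    dur_s <- n / fs

    # ground-truth fracture events (descents only, binomial second-bite thinning)
    ev_time <- numeric(0); ev_cycle <- integer(0); ev_major <- logical(0)
    k1 <- if (archetype$fracture_event_rate > 0) {
      stats::rpois(1, archetype$fracture_event_rate * t_desc)
    } else 0L
    desc_t0 <- function(k) seg_start[[paste0("desc", k)]] / fs
    if (k1 > 0) {
      ev_time <- sort(stats::runif(k1, desc_t0(1), desc_t0(1) + t_desc))
      ev_cycle <- rep(1L, k1)
      ev_major <- rep(FALSE, k1)
    }
    if (ncyc >= 2 && k1 > 0) {
      k2 <- stats::rbinom(1, k1, archetype$second_bite_event_ratio)
      if (k2 > 0) {
        t2 <- sort(stats::runif(k2, desc_t0(2), desc_t0(2) + t_desc))
        ev_time <- c(ev_time, t2)
        ev_cycle <- c(ev_cycle, rep(2L, k2))
        ev_major <- c(ev_major, rep(FALSE, k2))
      }
    }
    # major fracture near the end of the first descent
    if (archetype$brittleness > 0) {
      ev_time <- c(ev_time, desc_t0(1) + 0.92 * t_desc)
      ev_cycle <- c(ev_cycle, 1L)
      ev_major <- c(ev_major, TRUE)
    }
    o <- order(ev_time)
    events <- data.frame(
      time_s = ev_time[o], cycle = ev_cycle[o], major = ev_major[o]
    )
    nev <- nrow(events)
    events$vib_amp_V <- events$sound_amp_Pa <- numeric(nev)
    if (nev > 0) {
      jit <- stats::runif(nev, 0.6, 1)
      events$vib_amp_V <- archetype$vibration_spike_amp_V * jit *
        ifelse(events$major, 1.5, 1)
      events$sound_amp_Pa <- archetype$sound_spike_amp_Pa * jit *
        ifelse(events$major, 1.5, 1)
    }

    # force: peak * (depth/travel)^1.5 per cycle; the major fracture drops the
    # remaining cycle-1 force by `brittleness` and the second-cycle envelope
    # to 0.9*(1-brittleness); ordinary events add short transient dips.
    force <- numeric(n)
    rel <- actuation / travel
    b <- archetype$brittleness
    for (k in seq_len(ncyc)) {
      i0 <- seg_start[[paste0("desc", k)]]
      idx <- (i0 + 1L):(i0 + 2L * nd)          # descent + ascent
      pk <- if (k == 1L) archetype$peak_force_N else
        archetype$peak_force_N * 0.9 * (1 - b)
      fseg <- pk * rel[idx]^1.5
      if (k == 1L && b > 0) {
        tfrac <- desc_t0(1) + 0.92 * t_desc
        drop_from <- which(time_s[idx] >= tfrac)
        fseg[drop_from] <- fseg[drop_from] * (1 - b)
      }
      force[idx] <- fseg
    }
    # transient event dips (10 ms triangular, depth 0.12*b of local force)
    if (nev > 0 && b > 0) {
      hw <- max(1L, round(0.005 * fs))
      dip <- c(seq(0, 1, length.out = hw), seq(1, 0, length.out = hw))
      for (j in which(!events$major)) {
        i0 <- round(events$time_s[j] * fs)
        ii <- i0 + seq_along(dip) - hw
        keep <- ii >= 1L & ii <= n
        force[ii[keep]] <- force[ii[keep]] * (1 - 0.12 * b * dip[keep])
      }
    }
    # adhesive tail: negative half-sine, 50 ms, right after cycle-1 ascent
    if (archetype$adhesive_force_N > 0 && ncyc >= 2) {
      i0 <- seg_start[["pause1"]]
      na <- min(round(0.05 * fs), np)
      if (na > 1) {
        force[(i0 + 1L):(i0 + na)] <- -archetype$adhesive_force_N *
          sin(pi * seq(0, 1, length.out = na))
      }
    }

    vibration <- render_bursts(n, fs, events$time_s, events$vib_amp_V,
                               archetype$vib_carrier_Hz)
    ns <- round(dur_s * sfs)
    sound <- render_bursts(ns, sfs, events$time_s, events$sound_amp_Pa,
                           archetype$sound_carrier_Hz)
    if (cfg$vib_noise_sd_V > 0) {
      vibration <- vibration + stats::rnorm(n, 0, cfg$vib_noise_sd_V)
    }
    if (cfg$sound_noise_sd_Pa > 0) {
      sound <- sound + stats::rnorm(ns, 0, cfg$sound_noise_sd_Pa)
    }

    structure(
      list(
        force = force, vibration = vibration, sound = sound,
        actuation = actuation,
        force_fs_Hz = fs, sound_fs_Hz = sfs,
        baseline_n = nb, baseline_n_sound = round(cfg$baseline_s * sfs),
        events = events,
        sample_id = archetype$sample_id,
        condition = as.integer(condition),
        replicate = as.integer(replicate),
        seed = as.integer(seed)
      ),
      class = "chew_recording"
    )
  })
}

# Add decaying-sinusoid bursts (carrier f_Hz, 1 ms decay, hard 4 ms support)
# at the given times/amplitudes onto a zero series of length n at rate fs.
render_bursts <- function(n, fs, times, amps, f_Hz, tau_s = 0.001,
                          support_s = 0.004) {
  x <- numeric(n)
  if (length(times) == 0L) return(x)
  m <- max(2L, round(support_s * fs))
  tloc <- (seq_len(m) - 1L) / fs
  shape <- exp(-tloc / tau_s) * sin(2 * pi * f_Hz * tloc)
  for (j in seq_along(times)) {
    i0 <- round(times[j] * fs) + 1L
    ii <- i0:(i0 + m - 1L)
    keep <- ii >= 1L & ii <= n
    x[ii[keep]] <- x[ii[keep]] + amps[j] * shape[keep]
  }
  x
}

#' @export
print.chew_recording <- function(x, ...) {
  cat(sprintf(
    "<chew_recording> %s cond %d rep %d: %.2f s, %d fracture events\n",
    x$sample_id, x$condition, x$replicate,
    length(x$force) / x$force_fs_Hz, nrow(x$events)))
  invisible(x)
}

#' Simulate a sensory-panel study
#'
#' Generates the full factorial table of line-scale scores
#' (panelist x sample x condition x texture x replicate). Each score is
#' `clip(latent intensity + condition effect + panelist bias + noise, 0, 120)`
#' where the panelist bias is drawn once per panelist per texture and the
#' noise is i.i.d. Gaussian with SD `panel_sd`.
#'
#' @param archetypes List of [sample_archetype] objects.
#' @param effects 4 x 3 matrix of additive condition effects (rows
#'   [TEXTURES], columns conditions; column 1 must be all zero). Default
#'   [default_condition_effects()].
#' @param n_panelists,n_reps Panel size and replicate count (study defaults
#'   10 and 5).
#' @param panel_sd Within-panelist score noise SD on the 0-120 scale.
#' @param panelist_bias_sd SD of the per-panelist per-texture additive bias.
#' @param seed Integer seed.
#' @return An object of class `sensory_study`: list with `scores` (tidy
#'   data.frame: panelist, sample_id, condition, texture, replicate, value)
#'   and the generating parameters.
#' @export
simulate_sensory_study <- function(archetypes,
                                   effects = default_condition_effects(),
                                   n_panelists = 10, n_reps = 5,
                                   panel_sd = 8, panelist_bias_sd = 5,
                                   seed = 1L) {
  stopifnot(length(archetypes) >= 1)
  if (is.null(rownames(effects)) || !all(TEXTURES %in% rownames(effects)) ||
      ncol(effects) < 3 || anyNA(effects[TEXTURES, 1:3])) {
    stop("invalid-config: effects must be defined for every (texture, ",
         "condition) pair", call. = FALSE)
  }
  if (any(effects[TEXTURES, 1] != 0)) {
    stop("invalid-config: condition-1 effects must be 0 (reference)",
         call. = FALSE)
  }
  if (panel_sd < 0 || panelist_bias_sd < 0) {
    stop("invalid-config: SDs must be >= 0", call. = FALSE)
  }
  with_seed(seed, {
    bias <- matrix(stats::rnorm(n_panelists * length(TEXTURES),
                                0, panelist_bias_sd),
                   nrow = n_panelists,
                   dimnames = list(NULL, TEXTURES))
    grid <- expand.grid(
      replicate = seq_len(n_reps),
      texture = TEXTURES,
      condition = 1:3,
      sample_id = vapply(archetypes, function(a) a$sample_id, character(1)),
      panelist = seq_len(n_panelists),
      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
    )
    latent <- vapply(archetypes, function(a) a$true_texture_intensity,
                     numeric(length(TEXTURES)))
    colnames(latent) <- vapply(archetypes, function(a) a$sample_id,
                               character(1))
    mu <- latent[cbind(match(grid$texture, TEXTURES),
                       match(grid$sample_id, colnames(latent)))] +
      effects[TEXTURES, 1:3][cbind(match(grid$texture, TEXTURES),
                                   grid$condition)] +
      bias[cbind(grid$panelist, match(grid$texture, TEXTURES))]
    value <- mu + stats::rnorm(nrow(grid), 0, panel_sd)
    grid$value <- pmin(pmax(value, 0), 120)
    grid <- grid[, c("panelist", "sample_id", "condition", "texture",
                     "replicate", "value")]
    structure(
      list(scores = grid, effects = effects[TEXTURES, 1:3, drop = FALSE],
           panel_sd = panel_sd, panelist_bias_sd = panelist_bias_sd,
           n_panelists = n_panelists, n_reps = n_reps, seed = seed),
      class = "sensory_study"
    )
  })
}

#' Per-(sample, condition, texture) mean sensory scores
#'
#' The panel means used as the regression objective: for each cell, the mean
#' over panelists and replicates of the line-scale score.
#'
#' @param study A `sensory_study`.
#' @return data.frame with columns sample_id, condition, texture, mean_value.
#' @export
sensory_means <- function(study) {
  stopifnot(inherits(study, "sensory_study"))
  agg <- stats::aggregate(value ~ sample_id + condition + texture,
                          data = study$scores, FUN = mean)
  names(agg)[names(agg) == "value"] <- "mean_value"
  agg
}

#' Generate a complete synthetic study (recordings + sensory scores)
#'
#' Produces `n_reps` instrumental recordings per sample per condition (the
#' study design uses 15, i.e. 8 x 3 x 15 = 360 recordings) and a matching
#' sensory study, with all randomness derived from one seed. With
#' `out_dir` set, recordings and the manifest are written to disk (see
#' [write_recording()]); otherwise recordings are kept in memory, which is
#' only advisable for reduced configurations.
#'
#' @param archetypes List of [sample_archetype]s (default the eight study
#'   foods).
#' @param cfg A [chew_sim_config].
#' @param conditions Conditions to record (default 1:3).
#' @param n_reps Instrumental replicates per sample per condition
#'   (default 15).
#' @param effects,n_panelists,panel_n_reps,panel_sd,panelist_bias_sd Passed
#'   to [simulate_sensory_study()].
#' @param seed Global seed.
#' @param out_dir Optional output directory.
#' @return List with `recordings` (list of `chew_recording`, NULL when
#'   `out_dir` given), `sensory` (`sensory_study`) and `manifest`
#'   (data.frame: recording_id, sample_id, condition, replicate, seed and,
#'   when written, file paths).
#' @export
generate_study <- function(archetypes = default_archetypes(),
                           cfg = chew_sim_config(),
                           conditions = 1:3,
                           n_reps = 15,
                           effects = default_condition_effects(),
                           n_panelists = 10, panel_n_reps = 5,
                           panel_sd = 8, panelist_bias_sd = 5,
                           seed = 1L,
                           out_dir = NULL) {
  if (length(archetypes) < 1) {
    stop("invalid-config: need at least one archetype", call. = FALSE)
  }
  manifest <- generate_manifest(archetypes, conditions, n_reps, seed)

  arch_by_id <- stats::setNames(
    archetypes, vapply(archetypes, function(a) a$sample_id, character(1)))
  make_one <- function(i) {
    simulate_recording(arch_by_id[[manifest$sample_id[i]]], cfg,
                       seed = manifest$seed[i],
                       condition = manifest$condition[i],
                       replicate = manifest$replicate[i])
  }

  sensory <- simulate_sensory_study(
    archetypes, effects = effects, n_panelists = n_panelists,
    n_reps = panel_n_reps, panel_sd = panel_sd,
    panelist_bias_sd = panelist_bias_sd,
    seed = derive_seed(seed, "sensory"))

  if (is.null(out_dir)) {
    recs <- lapply(seq_len(nrow(manifest)), make_one)
    return(list(recordings = recs, sensory = sensory, manifest = manifest))
  }
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)) {
    stop("I/O failure: cannot create output directory ", out_dir,
         call. = FALSE)
  }
  manifest$force_csv <- file.path(out_dir,
                                  paste0(manifest$recording_id, "_fv.csv"))
  manifest$sound_wav <- file.path(out_dir,
                                  paste0(manifest$recording_id, ".wav"))
  for (i in seq_len(nrow(manifest))) {
    write_recording(make_one(i), manifest$force_csv[i], manifest$sound_wav[i])
  }
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  utils::write.csv(sensory$scores, file.path(out_dir, "sensory.csv"),
                   row.names = FALSE)
  list(recordings = NULL, sensory = sensory, manifest = manifest)
}
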