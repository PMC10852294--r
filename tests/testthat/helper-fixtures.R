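# Shared fixtures: a small fast archetype/config pair for signal-level
# tests, and a constructor for hand-built recordings with known channels.

tiny_archetype <- function(...) {
  args <- utils::modifyList(
    list(sample_id = "T1", height_mm = 3, peak_force_N = 10,
         brittleness = 0.5, fracture_event_rate = 40,
         second_bite_event_ratio = 0.2,
         vibration_spike_amp_V = 0.5, sound_spike_amp_Pa = 0.2,
         adhesive_force_N = 0.3,
         vib_carrier_Hz = 800, sound_carrier_Hz = 3000),
    list(...))
  do.call(sample_archetype, args)
}

# Sound rate reduced to 32 kHz: still above twice the top one-third-octave
# band edge, so no band is dropped, but records are ~40% lighter.
tiny_cfg <- function(...) {
  args <- utils::modifyList(
    list(sound_fs_Hz = 32000, baseline_s = 0.25, pause_s = 0.15,
         tail_s = 0.05),
    list(...))
  do.call(chew_sim_config, args)
}

# Hand-built recording around explicit channels. Default force/actuation is
# a clean two-hump curve so segment_cycles() finds exactly two cycles.
new_test_recording <- function(vibration, sound = NULL,
                               fs = 10000, sfs = 10000,
                               baseline_n = 1000,
                               force = NULL, actuation = NULL,
                               condition = 1L) {
  n <- length(vibration)
  if (is.null(actuation)) {
    nb <- baseline_n
    body <- n - nb
    seg <- body %/% 4L
    actuation <- c(rep(0, nb),
                   seq(0, 1, length.out = seg), seq(1, 0, length.out = seg),
                   rep(0, body - 4L * seg),
                   seq(0, 1, length.out = seg), seq(1, 0, length.out = seg))
    actuation <- actuation[seq_len(n)]
  }
  if (is.null(force)) force <- actuation * 10
  if (is.null(sound)) sound <- numeric(round(n * sfs / fs))
  structure(
    list(force = force, vibration = vibration, sound = sound,
         actuation = actuation, force_fs_Hz = fs, sound_fs_Hz = sfs,
         baseline_n = baseline_n,
         baseline_n_sound = round(baseline_n * sfs / fs),
         events = data.frame(), sample_id = "H1",
         condition = condition, replicate = 1L, seed = NA_integer_),
    class = "chew_recording"
  )
}

# Feature table with schema columns but synthetic values, for dataset-shape
# tests that do not need real signal extraction.
synthetic_feature_table <- function(sample_ids, conditions, n_reps,
                                    seed = 1L) {
  grid <- expand.grid(replicate = seq_len(n_reps), condition = conditions,
                      sample_id = sample_ids, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  set.seed(seed)
  X <- matrix(stats::rnorm(nrow(grid) * 66), nrow(grid), 66,
              dimnames = list(NULL, feature_schema()))
  X <- t(apply(cbind(grid$condition, X), 1, function(r) {
    mask_by_condition(r[-1], r[1])
  }))
  colnames(X) <- feature_schema()
  cbind(
    data.frame(recording_id = sprintf("%s_c%d_r%02d", grid$sample_id,
                                      grid$condition, grid$replicate),
               sample_id = grid$sample_id, condition = grid$condition,
               replicate = grid$replicate, stringsAsFactors = FALSE),
    as.data.frame(X))
}

# Noiseless sensory study whose scores equal the archetype intensities.
flat_sensory <- function(archetypes, n_panelists = 2, n_reps = 2) {
  simulate_sensory_study(
    archetypes, effects = default_condition_effects() * 0,
    n_panelists = n_panelists, n_reps = n_reps,
    panel_sd = 0, panelist_bias_sd = 0, seed = 1)
}
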