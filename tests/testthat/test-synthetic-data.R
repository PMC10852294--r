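test_that("noise-free eventless recording is a smooth two-hump force with silent channels", {
  a <- tiny_archetype(brittleness = 0, fracture_event_rate = 0,
                      adhesive_force_N = 0)
  cfg <- tiny_cfg(vib_noise_sd_V = 0, sound_noise_sd_Pa = 0)
  r <- simulate_recording(a, cfg, seed = 7)
  expect_identical(r$vibration, numeric(length(r$vibration)))
  expect_identical(r$sound, numeric(length(r$sound)))
  bounds <- segment_cycles(r$force, r$actuation)
  expect_length(bounds, 2L)
  m1 <- max(r$force[bounds[[1]][1]:bounds[[1]][2]])
  m2 <- max(r$force[bounds[[2]][1]:bounds[[2]][2]])
  expect_gt(m1, 0)
  expect_lte(m2, m1)
})

test_that("fixed seed gives bit-identical recordings", {
  a <- tiny_archetype()
  cfg <- tiny_cfg()
  r1 <- simulate_recording(a, cfg, seed = 42)
  r2 <- simulate_recording(a, cfg, seed = 42)
  expect_identical(r1, r2)
  r3 <- simulate_recording(a, cfg, seed = 43)
  expect_false(identical(r1$events, r3$events))
})

test_that("second compression carries brittleness-reduced force and the adhesive tail appears", {
  a <- tiny_archetype(brittleness = 0.5, adhesive_force_N = 0.4,
                      fracture_event_rate = 0)
  cfg <- tiny_cfg(vib_noise_sd_V = 0, sound_noise_sd_Pa = 0)
  r <- simulate_recording(a, cfg, seed = 1)
  bounds <- segment_cycles(r$force, r$actuation)
  m1 <- max(r$force[bounds[[1]][1]:bounds[[1]][2]])
  m2 <- max(r$force[bounds[[2]][1]:bounds[[2]][2]])
  expect_lt(m2, m1)
  gap <- (bounds[[1]][2] + 1):(bounds[[2]][1] - 1)
  expect_equal(min(r$force[gap]), -0.4, tolerance = 1e-4)
})

test_that("rendered force maximum increases strictly with peak_force_N", {
  cfg <- tiny_cfg(vib_noise_sd_V = 0, sound_noise_sd_Pa = 0)
  maxima <- vapply(c(5, 10, 20, 40), function(p) {
    max(simulate_recording(tiny_archetype(peak_force_N = p),
                           cfg, seed = 3)$force)
  }, numeric(1))
  expect_true(all(diff(maxima) > 0))
})

test_that("second-bite thinning reproduces the configured event ratio across seeds", {
  # expected 200 first-cycle events per recording, thinned at 0.1
  a <- tiny_archetype(height_mm = 6.25, fracture_event_rate = 400,
                      second_bite_event_ratio = 0.1, brittleness = 0)
  cfg <- tiny_cfg(sound_fs_Hz = 8000, vib_noise_sd_V = 0,
                  sound_noise_sd_Pa = 0)
  n1 <- n2 <- 0
  for (s in 1:50) {
    ev <- simulate_recording(a, cfg, seed = s)$events
    n1 <- n1 + sum(ev$cycle == 1)
    n2 <- n2 + sum(ev$cycle == 2)
  }
  # binomial sampling bound: 3 * sqrt(p(1-p)/n1)
  expect_lt(abs(n2 / n1 - 0.1), 3 * sqrt(0.1 * 0.9 / n1))
})

test_that("invalid simulator configs are rejected", {
  expect_error(sample_archetype("X", height_mm = -1, peak_force_N = 1),
               "invalid-config")
  expect_error(sample_archetype("X", height_mm = 1, peak_force_N = 1,
                                fracture_event_rate = -5),
               "invalid-config")
  expect_error(chew_sim_config(travel_fraction = 0), "invalid-config")
  expect_error(chew_sim_config(force_fs_Hz = -1), "invalid-config")
})

test_that("noiseless flat sensory study returns the latent intensities exactly", {
  archs <- list(tiny_archetype(sample_id = "A",
                               true_texture_intensity = stats::setNames(
                                 c(10, 40, 70, 100), TEXTURES)))
  st <- flat_sensory(archs)
  for (tex in TEXTURES) {
    expect_true(all(st$scores$value[st$scores$texture == tex] ==
                      archs[[1]]$true_texture_intensity[[tex]]))
  }
})

test_that("sensory scores are clipped to the 0-120 line scale", {
  archs <- list(tiny_archetype(sample_id = "A",
                               true_texture_intensity = stats::setNames(
                                 c(115, 115, 115, 2), TEXTURES)))
  eff <- default_condition_effects() * 0
  eff["paripari", 3] <- 30    # pushes the latent 115 over the top anchor
  eff["zakuzaku", 3] <- -30   # and the latent 2 below the bottom anchor
  st <- simulate_sensory_study(archs, effects = eff, n_panelists = 4,
                               n_reps = 3, panel_sd = 10,
                               panelist_bias_sd = 5, seed = 2)
  expect_true(all(st$scores$value >= 0 & st$scores$value <= 120))
  pp3 <- st$scores$value[st$scores$texture == "paripari" &
                           st$scores$condition == 3]
  expect_lte(mean(pp3), 120)
})

test_that("default condition effects push karikari and paripari up in condition 3", {
  archs <- default_archetypes()
  st <- simulate_sensory_study(archs, n_panelists = 10, n_reps = 5,
                               panel_sd = 2, panelist_bias_sd = 1, seed = 5)
  sm <- sensory_means(st)
  for (tex in c("karikari", "paripari")) {
    d <- merge(sm[sm$texture == tex & sm$condition == 3, ],
               sm[sm$texture == tex & sm$condition == 1, ],
               by = "sample_id")
    expect_gt(mean(d$mean_value.x - d$mean_value.y), 0)
  }
  for (tex in c("sakusaku", "zakuzaku")) {
    d <- merge(sm[sm$texture == tex & sm$condition == 3, ],
               sm[sm$texture == tex & sm$condition == 1, ],
               by = "sample_id")
    expect_lt(mean(d$mean_value.x - d$mean_value.y), 0)
  }
})

test_that("sensory study covers the full factorial design", {
  archs <- list(tiny_archetype(sample_id = "A"),
                tiny_archetype(sample_id = "B"))
  st <- simulate_sensory_study(archs, n_panelists = 3, n_reps = 2,
                               panel_sd = 1, seed = 1)
  expect_equal(nrow(st$scores), 3 * 2 * 3 * 4 * 2)
  counts <- table(st$scores$panelist, st$scores$sample_id,
                  st$scores$condition, st$scores$texture)
  expect_true(all(counts == 2))
})

test_that("missing condition-effect entries are rejected", {
  archs <- list(tiny_archetype())
  bad <- default_condition_effects()[, 1:2]
  expect_error(simulate_sensory_study(archs, effects = bad),
               "invalid-config")
})

test_that("generate_study produces the requested design and manifest", {
  a <- tiny_archetype(fracture_event_rate = 10)
  cfg <- tiny_cfg(sound_fs_Hz = 8000)
  st <- generate_study(list(a), cfg, conditions = 1L, n_reps = 3,
                       n_panelists = 2, panel_n_reps = 2, seed = 9)
  expect_length(st$recordings, 3L)
  expect_equal(nrow(st$manifest), 3L)
  expect_equal(st$manifest$recording_id,
               vapply(st$recordings, function(r) {
                 sprintf("%s_c%d_r%02d", r$sample_id, r$condition,
                         r$replicate)
               }, character(1)))
})
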