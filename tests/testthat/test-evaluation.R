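make_cluster_dataset <- function(n_per = 3, centers = c(0, 5, 10),
                                 y = c(20, 60, 100), noise = 0.1,
                                 seed = 1) {
  set.seed(seed)
  X <- matrix(0, n_per * length(centers), 66,
              dimnames = list(NULL, feature_schema()))
  ys <- numeric(nrow(X))
  meta <- data.frame(sample_id = character(nrow(X)),
                     condition = 1L, stringsAsFactors = FALSE)
  for (k in seq_along(centers)) {
    rows <- (k - 1) * n_per + seq_len(n_per)
    X[rows, 1:5] <- centers[k] + stats::rnorm(n_per * 5, sd = noise)
    ys[rows] <- y[k]
    meta$sample_id[rows] <- paste0("S", k)
  }
  structure(list(X = X, y = ys, meta = meta, texture = "sakusaku"),
            class = "modeling_dataset")
}

test_that("mae computes the mean absolute error and validates inputs", {
  expect_equal(mae(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mae(c(0, 10), c(5, 5)), 5)
  expect_error(mae(1:3, 1:2), "length mismatch")
  expect_error(mae(numeric(0), numeric(0)), "length mismatch")
})

test_that("loocv performs exactly N fits and keeps row metadata", {
  ds <- make_cluster_dataset()
  rep <- loocv(ds, hyper_policy = list(theta1 = 1, theta2 = 5,
                                       sigma_n = 0.1))
  expect_equal(rep$n_folds, 9L)
  expect_equal(nrow(rep$predictions), 9L)
  expect_identical(rep$predictions$sample_id, ds$meta$sample_id)
  # replicated clusters predict each other: far better than the baseline
  expect_lt(loocv_mae(rep), mae(rep$predictions$truth,
                                rep$predictions$baseline_pred))
})

test_that("loocv with N = 2 trains each fold on one row", {
  ds <- make_cluster_dataset(n_per = 1, centers = c(0, 5), y = c(10, 20))
  rep <- loocv(ds, hyper_policy = list(theta1 = 1, theta2 = 1,
                                       sigma_n = 0), scale = FALSE)
  expect_equal(rep$n_folds, 2L)
  expect_error(loocv(make_cluster_dataset(n_per = 1, centers = 0, y = 1)),
               "N >= 2")
})

test_that("constant objectives are predicted almost exactly", {
  ds <- make_cluster_dataset(y = c(50, 50, 50))
  rep <- loocv(ds, hyper_policy = list(theta1 = 1e4, theta2 = 50,
                                       sigma_n = 1))
  expect_lt(loocv_mae(rep), 0.5)
  expect_equal(rep$predictions$pred_mean, rep(50, 9), tolerance = 0.02)
})

test_that("permuting dataset rows permutes loocv predictions identically", {
  ds <- make_cluster_dataset(noise = 0.5, seed = 3)
  hp <- list(theta1 = 2, theta2 = 10, sigma_n = 0.2)
  r1 <- loocv(ds, hyper_policy = hp)
  perm <- c(4, 9, 1, 7, 2, 6, 3, 8, 5)
  ds2 <- structure(list(X = ds$X[perm, ], y = ds$y[perm],
                        meta = ds$meta[perm, ], texture = ds$texture),
                   class = "modeling_dataset")
  r2 <- loocv(ds2, hyper_policy = hp)
  expect_equal(r2$predictions$pred_mean, r1$predictions$pred_mean[perm],
               tolerance = 1e-10)
})

test_that("the mae table has the frozen report layout", {
  ds <- make_cluster_dataset()
  ds$meta$condition <- rep(1:3, 3)
  hp <- list(theta1 = 1, theta2 = 5, sigma_n = 0.1)
  reports <- list(sakusaku = loocv(ds, hp), karikari = loocv(ds, hp))
  tab <- mae_table(reports)
  expect_identical(rownames(tab),
                   c("Condition 1", "Condition 2", "Condition 3", "Mean"))
  expect_identical(names(tab), c("sakusaku", "karikari"))
  expect_true(all(tab >= 0))
  expect_equal(tab["Mean", "sakusaku"], loocv_mae(reports$sakusaku))
})

test_that("prediction summaries aggregate by sample and condition", {
  ds <- make_cluster_dataset()
  rep <- loocv(ds, hyper_policy = list(theta1 = 1, theta2 = 5,
                                       sigma_n = 0.1))
  s <- prediction_summary(rep)
  expect_equal(nrow(s), 3L)
  expect_equal(s$n, rep(3L, 3))
  expect_true(all(is.finite(s$pred_sd)))
})

test_that("condition contrasts flag a large shift and keep p-values in [0,1]", {
  arch <- tiny_archetype(true_texture_intensity = stats::setNames(
    c(60, 60, 60, 60), TEXTURES))
  eff <- default_condition_effects() * 0
  eff["paripari", 3] <- 30
  st <- simulate_sensory_study(list(arch), effects = eff, n_panelists = 10,
                               n_reps = 5, panel_sd = 5,
                               panelist_bias_sd = 0, seed = 3)
  ct <- condition_contrasts(st, n_perm = 500, seed = 1)
  expect_true(all(ct$p_adj >= 0 & ct$p_adj <= 1))
  hit <- ct[ct$texture == "paripari" & ct$pair == "1-3", ]
  expect_true(hit$significant)
  expect_equal(hit$mean_diff, -30, tolerance = 5)
})

test_that("identical score distributions are rarely flagged", {
  arch <- tiny_archetype()
  flags <- 0
  n_runs <- 20
  for (s in seq_len(n_runs)) {
    st <- simulate_sensory_study(list(arch),
                                 effects = default_condition_effects() * 0,
                                 n_panelists = 5, n_reps = 3, panel_sd = 8,
                                 panelist_bias_sd = 0, seed = 100 + s)
    ct <- condition_contrasts(st, n_perm = 300, seed = s)
    one <- ct[ct$texture == "sakusaku", ]
    if (any(one$significant)) flags <- flags + 1
  }
  # familywise alpha = 0.05 per cell: 20 null runs should rarely flag
  expect_lte(flags, 3)
})

test_that("cells with too few replicates are skipped with a warning", {
  arch <- tiny_archetype()
  st <- simulate_sensory_study(list(arch), n_panelists = 1, n_reps = 1,
                               panel_sd = 1, seed = 1)
  w <- capture_warnings(ct <- condition_contrasts(st, n_perm = 50, seed = 1))
  expect_match(w, "fewer than 2", all = TRUE)
  expect_length(w, 4L)                     # one per texture cell
  expect_null(ct)
})
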