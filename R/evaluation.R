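#' Mean absolute error
#'
#' @param truth,pred Equal-length nonempty numeric vectors.
#' @return Mean of `|truth - pred|`. On the study's 0-120 line scale an MAE
#'   of 6 corresponds to 5% of the range.
#' @export
mae <- function(truth, pred) {
  if (length(truth) != length(pred) || length(truth) == 0L) {
    stop("length mismatch or empty input", call. = FALSE)
  }
  mean(abs(truth - pred))
}

#' Leave-one-out cross-validation of the GPR pipeline
#'
#' For each row i of the dataset a model is trained on the other N-1 rows
#' and row i is predicted, so exactly N fits and predictions are performed.
#' The feature scaler is re-fitted inside every fold on the N-1 training
#' rows only (no leakage). Hyperparameter policies:
#' * `"frozen"` (default): one evidence optimization on the full
#'   standardized dataset, hyperparameters then held fixed across folds
#'   (the kernel matrix itself is still rebuilt per fold);
#' * `"per_fold"`: evidence optimization repeated inside every fold;
#' * a list `(theta1, theta2, sigma_n)`: used as-is in every fold.
#'
#' @param dataset A `modeling_dataset` from [build_dataset()].
#' @param hyper_policy `"frozen"`, `"per_fold"`, or an explicit
#'   hyperparameter list.
#' @param scale Standardize features per fold (default TRUE).
#' @param seed Seed for the hyperparameter multi-starts.
#' @param baseline Also compute the mean-predictor baseline (training-fold
#'   mean of y as the prediction; default TRUE).
#' @return An object of class `loocv_report`: list with `predictions`
#'   (metadata + truth, pred_mean, pred_var, baseline_pred), `texture`,
#'   `hyper` (hyperparameters used; per-fold list when re-optimized),
#'   `n_folds`.
#' @export
loocv <- function(dataset, hyper_policy = "frozen", scale = TRUE,
                  seed = 1L, baseline = TRUE) {
  stopifnot(inherits(dataset, "modeling_dataset"))
  X <- dataset$X
  y <- dataset$y
  n <- nrow(X)
  if (n < 2L) stop("LOOCV needs N >= 2", call. = FALSE)

  frozen_hp <- NULL
  if (identical(hyper_policy, "frozen")) {
    Xs <- if (scale) standardize(X)$train else X
    m <- gpr_fit(Xs, y, hyper = "optimize", seed = seed)
    frozen_hp <- list(theta1 = m$theta1, theta2 = m$theta2,
                      sigma_n = m$sigma_n)
  } else if (!identical(hyper_policy, "per_fold")) {
    frozen_hp <- as.list(hyper_policy)
  }

  pred_mean <- pred_var <- base_pred <- numeric(n)
  per_fold_hp <- if (is.null(frozen_hp)) vector("list", n) else NULL
  for (i in seq_len(n)) {
    Xtr <- X[-i, , drop = FALSE]
    Xte <- X[i, , drop = FALSE]
    if (scale) {
      sc <- standardize(Xtr, Xte)
      Xtr <- sc$train; Xte <- sc$apply
    }
    fit <- tryCatch(
      gpr_fit(Xtr, y[-i],
              hyper = if (is.null(frozen_hp)) "optimize" else frozen_hp,
              seed = derive_seed(seed, paste0("fold", i))),
      error = function(e) {
        stop("LOOCV fold ", i, " failed: ", conditionMessage(e),
             call. = FALSE)
      })
    p <- gpr_predict(fit, Xte)
    pred_mean[i] <- p$mean
    pred_var[i] <- p$variance
    if (baseline) base_pred[i] <- mean(y[-i])
    if (!is.null(per_fold_hp)) {
      per_fold_hp[[i]] <- list(theta1 = fit$theta1, theta2 = fit$theta2,
                               sigma_n = fit$sigma_n)
    }
  }
  predictions <- cbind(
    dataset$meta,
    data.frame(truth = y, pred_mean = pred_mean, pred_var = pred_var)
  )
  if (baseline) predictions$baseline_pred <- base_pred
  structure(
    list(predictions = predictions, texture = dataset$texture,
         hyper = frozen_hp %||% per_fold_hp, n_folds = n),
    class = "loocv_report"
  )
}

#' MAE of an LOOCV report, overall or by condition
#'
#' @param report A `loocv_report`.
#' @param by `"overall"` or `"condition"`.
#' @param which Column to score: `"pred_mean"` (model) or `"baseline_pred"`.
#' @return Scalar MAE, or a named vector per condition.
#' @export
loocv_mae <- function(report, by = c("overall", "condition"),
                      which = "pred_mean") {
  by <- match.arg(by)
  p <- report$predictions
  if (by == "overall") return(mae(p$truth, p[[which]]))
  vapply(split(p, p$condition),
         function(d) mae(d$truth, d[[which]]), numeric(1))
}

#' Assemble the per-texture, per-condition MAE table
#'
#' The standard report layout: one column per texture, one row per sensory
#' condition plus a bottom `Mean` row averaging over the whole dataset of
#' that texture.
#'
#' @param reports Named list of `loocv_report`s (names = textures).
#' @param which Column to score (see [loocv_mae()]).
#' @return data.frame with rownames `Condition 1..3` and `Mean`.
#' @export
mae_table <- function(reports, which = "pred_mean") {
  cols <- lapply(reports, function(r) {
    c(loocv_mae(r, "condition", which = which),
      Mean = loocv_mae(r, "overall", which = which))
  })
  out <- as.data.frame(cols)
  names(out) <- names(reports)
  rownames(out) <- c(paste("Condition", names(cols[[1]])[-length(cols[[1]])]),
                     "Mean")
  out
}

#' Per-(sample, condition) prediction summaries
#'
#' Mean and SD of the LOOCV predicted values per (sample, condition) cell,
#' with the cell's sensory truth alongside -- the numbers behind a
#' prediction-vs-truth plot with SD error bars.
#'
#' @param report A `loocv_report`.
#' @return data.frame: sample_id, condition, truth, pred_mean, pred_sd, n.
#' @export
prediction_summary <- function(report) {
  p <- report$predictions
  agg <- do.call(rbind, lapply(
    split(p, list(p$sample_id, p$condition), drop = TRUE),
    function(d) data.frame(
      sample_id = d$sample_id[1], condition = d$condition[1],
      truth = d$truth[1], pred_mean = mean(d$pred_mean),
      pred_sd = stats::sd(d$pred_mean), n = nrow(d))))
  rownames(agg) <- NULL
  agg[order(agg$sample_id, agg$condition), ]
}

#' Pairwise condition comparisons by max-T permutation test
#'
#' For each (sample, texture) cell the three condition-pair mean differences
#' are tested with a familywise max-T permutation procedure: condition
#' labels are permuted within the cell, the null statistic is the maximum
#' absolute pair mean-difference over the three pairs, and each pair's
#' adjusted p-value is the fraction of permutations whose max-T reaches the
#' pair's observed difference. This keeps the familywise error at `alpha`
#' across the three pairs of a cell.
#'
#' @param sensory A `sensory_study`.
#' @param alpha Significance level for flagging (default 0.05).
#' @param n_perm Number of permutations (default 10000).
#' @param seed Seed.
#' @return data.frame: sample_id, texture, pair, mean_diff, p_adj,
#'   significant.
#' @export
condition_contrasts <- function(sensory, alpha = 0.05, n_perm = 10000,
                                seed = 1L) {
  stopifnot(inherits(sensory, "sensory_study"))
  sc <- sensory$scores
  pairs <- list(c(1, 2), c(1, 3), c(2, 3))
  out <- list()
  with_seed(derive_seed(seed, "contrasts"), {
    for (sid in unique(sc$sample_id)) {
      for (tex in unique(sc$texture)) {
        cell <- sc[sc$sample_id == sid & sc$texture == tex, ]
        counts <- table(factor(cell$condition, levels = 1:3))
        if (any(counts < 2)) {
          warning("skipping ", sid, "/", tex,
                  ": fewer than 2 scores in some condition")
          next
        }
        x <- cell$value
        lab <- cell$condition
        obs <- vapply(pairs, function(pr) {
          abs(mean(x[lab == pr[1]]) - mean(x[lab == pr[2]]))
        }, numeric(1))
        signed <- vapply(pairs, function(pr) {
          mean(x[lab == pr[1]]) - mean(x[lab == pr[2]])
        }, numeric(1))
        maxT <- vapply(seq_len(n_perm), function(b) {
          xp <- x[sample.int(length(x))]
          max(vapply(pairs, function(pr) {
            abs(mean(xp[lab == pr[1]]) - mean(xp[lab == pr[2]]))
          }, numeric(1)))
        }, numeric(1))
        p_adj <- vapply(obs, function(t0) {
          (1 + sum(maxT >= t0)) / (n_perm + 1)
        }, numeric(1))
        out[[length(out) + 1L]] <- data.frame(
          sample_id = sid, texture = tex,
          pair = vapply(pairs, function(pr) paste(pr, collapse = "-"),
                        character(1)),
          mean_diff = signed, p_adj = p_adj,
          significant = p_adj < alpha)
      }
    }
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
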