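#' The frozen 66-feature schema
#'
#' Column names of the explanatory vector, in fixed order: 6 TPA force
#' features, 22 vibration features, 38 sound features.
#'
#' @return Character vector of length 66.
#' @export
feature_schema <- function() {
  c(paste0("tpa_", c("hardness", "fracturability", "adhesive_force",
                     "adhesiveness", "cohesiveness", "gumminess")),
    vibration_feature_names(),
    sound_feature_names())
}

# Block index helpers on the 66-column schema.
feature_blocks <- function() {
  list(tpa = 1:6, vibration = 7:28, sound = 29:66)
}

#' Extract the full 66-feature explanatory vector from one recording
#'
#' Runs the three extractors ([extract_tpa_features()],
#' [extract_vibration_features()], [extract_sound_features()]) on one
#' recording, concatenates the blocks in schema order and, unless
#' `mask = FALSE`, applies the condition mask ([mask_by_condition()]) for
#' the recording's condition tag.
#'
#' @param recording A `chew_recording`.
#' @param mask Apply the condition masking rule (default TRUE).
#' @param ... Passed through to the per-channel extractors.
#' @return Named numeric vector of length 66.
#' @export
extract_features <- function(recording, mask = TRUE, ...) {
  bounds <- segment_cycles(recording$force, recording$actuation)
  tpa <- extract_tpa_features(recording)
  vib <- extract_vibration_features(recording, cycle_bounds = bounds, ...)
  snd <- extract_sound_features(recording, cycle_bounds = bounds, ...)
  v <- stats::setNames(c(tpa, vib, snd), feature_schema())
  if (mask) v <- mask_by_condition(v, recording$condition)
  v
}

#' Apply the sensory-condition masking rule to a feature vector
#'
#' Condition 1 (normal) keeps all 66 features. Condition 2 (no air sound)
#' zeroes the 38 sound features. Condition 3 (only air sound) zeroes the 6
#' force and 22 vibration features. The zeros are meaningful inputs: they
#' encode the absence of a sensory channel for the regressor.
#'
#' @param values Named numeric vector of length 66 in schema order.
#' @param condition Condition code 1, 2 or 3.
#' @return Masked copy of `values`.
#' @export
mask_by_condition <- function(values, condition) {
  if (length(values) != 66L) {
    stop("feature vector must have length 66, got ", length(values),
         call. = FALSE)
  }
  if (!length(condition) == 1L || !condition %in% 1:3) {
    stop("unknown condition: ", paste(condition, collapse = ","),
         call. = FALSE)
  }
  blocks <- feature_blocks()
  if (condition == 2) {
    values[blocks$sound] <- 0
  } else if (condition == 3) {
    values[c(blocks$tpa, blocks$vibration)] <- 0
  }
  values
}

#' Extract the masked feature table for a set of recordings
#'
#' @param recordings List of `chew_recording` objects.
#' @param mask,... Passed to [extract_features()].
#' @return data.frame: recording_id, sample_id, condition, replicate + the
#'   66 schema columns.
#' @export
extract_feature_table <- function(recordings, mask = TRUE, ...) {
  rows <- lapply(recordings, function(r) {
    v <- extract_features(r, mask = mask, ...)
    cbind(
      data.frame(
        recording_id = sprintf("%s_c%d_r%02d", r$sample_id, r$condition,
                               r$replicate),
        sample_id = r$sample_id, condition = r$condition,
        replicate = r$replicate, stringsAsFactors = FALSE),
      as.data.frame(as.list(v), check.names = FALSE)
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pair feature vectors with panel-mean objectives for one texture
#'
#' Builds the modeling dataset for one texture descriptor: each row's
#' objective is the mean sensory score (over panelists and replicates) of
#' that texture for the row's (sample, condition) cell. The default
#' synthetic study (8 samples x 3 conditions x 15 instrumental replicates)
#' yields N = 360 rows, 120 per condition.
#'
#' @param features Feature table from [extract_feature_table()] (metadata +
#'   66 schema columns).
#' @param sensory A `sensory_study`.
#' @param texture One of [TEXTURES].
#' @return An object of class `modeling_dataset`: list with `X` (N x 66
#'   matrix), `y` (length N), `meta` (metadata data.frame) and `texture`.
#' @export
build_dataset <- function(features, sensory, texture) {
  texture <- match.arg(texture, TEXTURES)
  stopifnot(inherits(sensory, "sensory_study"))
  sm <- sensory_means(sensory)
  sm <- sm[sm$texture == texture, , drop = FALSE]
  key <- paste(features$sample_id, features$condition)
  skey <- paste(sm$sample_id, sm$condition)
  hit <- match(key, skey)
  if (anyNA(hit)) {
    stop("missing sensory cell(s): ",
         paste(unique(key[is.na(hit)]), collapse = ", "), call. = FALSE)
  }
  cols <- feature_schema()
  X <- as.matrix(features[, cols, drop = FALSE])
  if (any(!is.finite(X))) stop("non-finite feature values", call. = FALSE)
  structure(
    list(X = X, y = sm$mean_value[hit],
         meta = features[, setdiff(names(features), cols), drop = FALSE],
         texture = texture),
    class = "modeling_dataset"
  )
}

#' Fit a per-feature z-scoring scaler on training rows and apply it
#'
#' Standardizes each column with the training mean and SD only (so held-out
#' rows never leak into the scaler). Zero-variance training columns map to 0
#' in both the training and the applied matrices.
#'
#' @param train_X Training feature matrix.
#' @param apply_X Optional matrix to transform with the training statistics
#'   (defaults to `train_X`).
#' @return List: `train` (scaled training matrix), `apply` (scaled
#'   `apply_X`), `center`, `scale`, `zero_var` (logical per column).
#' @export
standardize <- function(train_X, apply_X = train_X) {
  train_X <- as.matrix(train_X)
  apply_X <- as.matrix(apply_X)
  if (nrow(train_X) == 0L) stop("empty training matrix", call. = FALSE)
  center <- colMeans(train_X)
  scl <- apply(train_X, 2, stats::sd)
  if (nrow(train_X) == 1L) scl[] <- 0
  zero_var <- !is.finite(scl) | scl == 0
  scl[zero_var] <- 1
  tr <- sweep(sweep(train_X, 2, center), 2, scl, "/")
  ap <- sweep(sweep(apply_X, 2, center), 2, scl, "/")
  tr[, zero_var] <- 0
  ap[, zero_var] <- 0
  list(train = tr, apply = ap, center = center, scale = scl,
       zero_var = zero_var)
}
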