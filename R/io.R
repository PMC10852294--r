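# Disk formats: force/vibration/actuation as CSV, sound as mono WAV
# (IEEE float32 written; PCM16 also read), features and sensory tables as
# CSV, configuration as YAML. A minimal WAV codec is implemented here
# because the package only needs mono read/write of two sample formats.

#' Write a chew recording to disk
#'
#' Force, vibration and actuation go to a 4-column CSV
#' (`time_s, force_N, vibration_V, actuation_mm`); sound goes to a mono
#' IEEE-float32 WAV at the recording's sampling rate.
#'
#' @param recording A `chew_recording`.
#' @param force_csv,sound_wav Output paths.
#' @return Invisibly, the recording.
#' @export
write_recording <- function(recording, force_csv, sound_wav) {
  stopifnot(inherits(recording, "chew_recording"))
  n <- length(recording$force)
  df <- data.frame(
    time_s = (seq_len(n) - 1L) / recording$force_fs_Hz,
    force_N = recording$force,
    vibration_V = recording$vibration,
    actuation_mm = recording$actuation
  )
  utils::write.csv(df, force_csv, row.names = FALSE)
  write_wav(recording$sound, recording$sound_fs_Hz, sound_wav)
  invisible(recording)
}

#' Read a chew recording from disk
#'
#' Counterpart of [write_recording()]. The ground-truth event log is a
#' simulator-internal object and does not round-trip; everything the feature
#' extractors need (channels, actuation, rates, baseline length) does.
#'
#' @param force_csv Path of the force/vibration/actuation CSV.
#' @param sound_wav Path of the mono sound WAV.
#' @param sound_fs_Hz Expected sound sampling rate; a mismatching file is an
#'   error (default 51200).
#' @param baseline_s Pre-motion baseline duration encoded in the recording.
#' @param sample_id,condition,replicate Metadata (e.g. from the manifest).
#' @return A `chew_recording`.
#' @export
read_recording <- function(force_csv, sound_wav, sound_fs_Hz = 51200,
                           baseline_s = 0.3,
                           sample_id = NA_character_, condition = 1L,
                           replicate = 1L) {
  if (!file.exists(force_csv)) {
    stop("missing input file: ", force_csv, call. = FALSE)
  }
  df <- utils::read.csv(force_csv)
  need <- c("time_s", "force_N", "vibration_V", "actuation_mm")
  if (!all(need %in% names(df))) {
    stop("schema violation in ", force_csv, ": expected columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  fs <- round(1 / stats::median(diff(df$time_s)))
  wav <- read_wav(sound_wav)
  if (wav$fs != sound_fs_Hz) {
    stop("WAV at wrong sample rate: ", wav$fs, " Hz, expected ",
         sound_fs_Hz, " Hz", call. = FALSE)
  }
  structure(
    list(force = df$force_N, vibration = df$vibration_V,
         sound = wav$samples, actuation = df$actuation_mm,
         force_fs_Hz = fs, sound_fs_Hz = wav$fs,
         baseline_n = round(baseline_s * fs),
         baseline_n_sound = round(baseline_s * wav$fs),
         events = data.frame(time_s = numeric(0), cycle = integer(0),
                             major = logical(0), vib_amp_V = numeric(0),
                             sound_amp_Pa = numeric(0)),
         sample_id = sample_id, condition = as.integer(condition),
         replicate = as.integer(replicate), seed = NA_integer_),
    class = "chew_recording"
  )
}

# -- minimal mono WAV codec ---------------------------------------------------

#' Write a mono IEEE-float32 WAV file
#'
#' @param samples Numeric vector.
#' @param fs Sampling rate (Hz).
#' @param path Output path.
#' @export
write_wav <- function(samples, fs, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(samples)
  data_bytes <- 4L * n
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(3L, con, size = 2, endian = "little")            # IEEE float
  writeBin(1L, con, size = 2, endian = "little")            # mono
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs * 4L), con, size = 4, endian = "little")
  writeBin(4L, con, size = 2, endian = "little")            # block align
  writeBin(32L, con, size = 2, endian = "little")           # bits/sample
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  writeBin(as.numeric(samples), con, size = 4, endian = "little")
  invisible(path)
}

#' Read a mono WAV file (PCM16 or IEEE float32)
#'
#' @param path Input path.
#' @return List with `samples` (numeric, PCM16 scaled to [-1, 1)) and `fs`.
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop("missing input file: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  readBin(con, "integer", 1, size = 4, endian = "little")
  wave <- readChar(con, 4, useBytes = TRUE)
  if (riff != "RIFF" || wave != "WAVE") {
    stop("schema violation: ", path, " is not a RIFF/WAVE file",
         call. = FALSE)
  }
  fmt <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (id == "fmt ") {
      raw <- readBin(con, "raw", sz)
      fmt <- list(
        format = readBin(raw[1:2], "integer", 1, size = 2,
                         endian = "little"),
        channels = readBin(raw[3:4], "integer", 1, size = 2,
                           endian = "little"),
        fs = readBin(raw[5:8], "integer", 1, size = 4, endian = "little"),
        bits = readBin(raw[15:16], "integer", 1, size = 2,
                       endian = "little")
      )
    } else if (id == "data") {
      if (is.null(fmt)) stop("schema violation: data before fmt chunk",
                             call. = FALSE)
      if (fmt$channels != 1L) {
        stop("only mono WAV supported, got ", fmt$channels, " channels",
             call. = FALSE)
      }
      if (fmt$format == 3L && fmt$bits == 32L) {
        samples <- readBin(con, "numeric", sz / 4L, size = 4,
                           endian = "little")
      } else if (fmt$format == 1L && fmt$bits == 16L) {
        samples <- readBin(con, "integer", sz / 2L, size = 2,
                           signed = TRUE, endian = "little") / 32768
      } else {
        stop("unsupported WAV encoding: format ", fmt$format, ", ",
             fmt$bits, " bits", call. = FALSE)
      }
      break
    } else {
      readBin(con, "raw", sz + sz %% 2L)
    }
  }
  if (is.null(samples)) stop("schema violation: no data chunk in ", path,
                             call. = FALSE)
  list(samples = samples, fs = fmt$fs)
}

# -- feature/report tables ----------------------------------------------------

#' Write a feature table with its frozen schema sidecar
#'
#' Writes the feature CSV and a JSON sidecar recording the 66-column schema
#' order, so readers can verify column order instead of trusting it.
#'
#' @param features Feature table ([extract_feature_table()]).
#' @param path CSV output path; the sidecar is `<path>.schema.json`.
#' @export
write_features <- function(features, path) {
  stopifnot(all(feature_schema() %in% names(features)))
  utils::write.csv(features, path, row.names = FALSE)
  jsonlite::write_json(
    list(feature_columns = feature_schema()),
    paste0(path, ".schema.json"))
  invisible(path)
}

#' Read a feature table, verifying the schema sidecar
#'
#' @param path CSV path written by [write_features()].
#' @return Feature data.frame.
#' @export
read_features <- function(path) {
  if (!file.exists(path)) stop("missing input file: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  sidecar <- paste0(path, ".schema.json")
  if (file.exists(sidecar)) {
    sch <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!identical(unname(sch$feature_columns), feature_schema())) {
      stop("schema violation: feature column order in ", sidecar,
           " does not match this package's frozen schema", call. = FALSE)
    }
  }
  miss <- setdiff(feature_schema(), names(df))
  if (length(miss)) {
    stop("schema violation: missing feature columns ",
         paste(utils::head(miss, 3), collapse = ", "), call. = FALSE)
  }
  df
}

# -- configuration ------------------------------------------------------------

#' Read a pipeline configuration from YAML
#'
#' Recognized top-level keys: `seed`, `archetypes` (list of
#' [sample_archetype()] argument lists), `sim` ([chew_sim_config()]
#' arguments), `study` (`n_reps`, `conditions`, `n_panelists`,
#' `panel_n_reps`, `panel_sd`, `panelist_bias_sd`), `features` (`k_sigma`,
#' `ma_window_s`, `peak_min_sep_s`, `frame_s`), `model` (`hyper_policy`,
#' `scale`). Unknown keys are rejected. Omitted keys take the package
#' defaults.
#'
#' @param path YAML file path.
#' @return A validated config list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("missing input file: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  known <- c("seed", "archetypes", "sim", "study", "features", "model")
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- list(
    seed = raw$seed %||% 1L,
    archetypes = if (is.null(raw$archetypes)) default_archetypes() else
      lapply(raw$archetypes, function(a) do.call(sample_archetype, a)),
    sim = do.call(chew_sim_config, raw$sim %||% list()),
    study = utils::modifyList(
      list(n_reps = 15, conditions = 1:3, n_panelists = 10,
           panel_n_reps = 5, panel_sd = 8, panelist_bias_sd = 5),
      raw$study %||% list()),
    features = utils::modifyList(
      list(k_sigma = 3, ma_window_s = 0.010, peak_min_sep_s = 0.005,
           frame_s = 0.05),
      raw$features %||% list()),
    model = utils::modifyList(
      list(hyper_policy = "frozen", scale = TRUE),
      raw$model %||% list())
  )
  structure(cfg, class = "pipeline_config")
}

# -- end-to-end pipeline ------------------------------------------------------

#' Run the full synthetic crispness study end to end
#'
#' Streams the whole pipeline from one seed: simulates every instrumental
#' recording of the study design (extracting its 66 masked features and
#' discarding the raw channels immediately, so the default 360-recording
#' study fits comfortably in memory), simulates the sensory panel, builds
#' one modeling dataset per texture and evaluates each with LOOCV.
#'
#' @param archetypes,cfg,n_reps,conditions Study design (defaults: the eight
#'   study foods, 15 replicates, conditions 1-3).
#' @param effects,n_panelists,panel_n_reps,panel_sd,panelist_bias_sd Sensory
#'   simulation parameters (see [simulate_sensory_study()]).
#' @param textures Textures to model (default all four).
#' @param hyper_policy,scale Passed to [loocv()].
#' @param seed Global seed; every stage derives its own seed from it.
#' @param out_dir Optional directory for the feature table, sensory table,
#'   per-texture prediction CSVs and the machine-readable MAE JSON.
#' @return List: `features`, `sensory`, `manifest`, `reports` (named list of
#'   `loocv_report`), `mae` (MAE table), `baseline_mae` (same layout for the
#'   mean-predictor baseline).
#' @export
run_crispness_study <- function(archetypes = default_archetypes(),
                                cfg = chew_sim_config(),
                                n_reps = 15, conditions = 1:3,
                                effects = default_condition_effects(),
                                n_panelists = 10, panel_n_reps = 5,
                                panel_sd = 8, panelist_bias_sd = 5,
                                textures = TEXTURES,
                                hyper_policy = "frozen", scale = TRUE,
                                seed = 1L, out_dir = NULL) {
  manifest <- generate_manifest(archetypes, conditions, n_reps, seed)
  arch_by_id <- stats::setNames(
    archetypes, vapply(archetypes, function(a) a$sample_id, character(1)))
  rows <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    rec <- simulate_recording(arch_by_id[[manifest$sample_id[i]]], cfg,
                              seed = manifest$seed[i],
                              condition = manifest$condition[i],
                              replicate = manifest$replicate[i])
    v <- extract_features(rec, mask = TRUE)
    rows[[i]] <- c(v)
  }
  features <- cbind(manifest[, c("recording_id", "sample_id", "condition",
                                 "replicate")],
                    as.data.frame(do.call(rbind, rows)))
  sensory <- simulate_sensory_study(
    archetypes, effects = effects, n_panelists = n_panelists,
    n_reps = panel_n_reps, panel_sd = panel_sd,
    panelist_bias_sd = panelist_bias_sd, seed = derive_seed(seed, "sensory"))
  reports <- lapply(stats::setNames(textures, textures), function(tex) {
    ds <- build_dataset(features, sensory, tex)
    loocv(ds, hyper_policy = hyper_policy, scale = scale,
          seed = derive_seed(seed, paste0("loocv/", tex)))
  })
  res <- list(features = features, sensory = sensory, manifest = manifest,
              reports = reports,
              mae = mae_table(reports),
              baseline_mae = mae_table(reports, which = "baseline_pred"))
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir) &&
        !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)) {
      stop("I/O failure: cannot create output directory ", out_dir,
           call. = FALSE)
    }
    write_features(features, file.path(out_dir, "features.csv"))
    utils::write.csv(sensory$scores, file.path(out_dir, "sensory.csv"),
                     row.names = FALSE)
    utils::write.csv(res$mae, file.path(out_dir, "mae.csv"))
    jsonlite::write_json(
      list(mae = res$mae, baseline_mae = res$baseline_mae),
      file.path(out_dir, "mae.json"), dataframe = "columns", digits = NA)
    for (tex in names(reports)) {
      utils::write.csv(reports[[tex]]$predictions,
                       file.path(out_dir, paste0("predictions_", tex, ".csv")),
                       row.names = FALSE)
    }
  }
  res
}

# Shared manifest builder (recording ids and derived per-recording seeds).
generate_manifest <- function(archetypes, conditions, n_reps, seed) {
  manifest <- expand.grid(
    replicate = seq_len(n_reps),
    condition = as.integer(conditions),
    sample_id = vapply(archetypes, function(a) a$sample_id, character(1)),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )[, c("sample_id", "condition", "replicate")]
  manifest <- manifest[order(manifest$sample_id, manifest$condition,
                             manifest$replicate), , drop = FALSE]
  rownames(manifest) <- NULL
  manifest$recording_id <- sprintf("%s_c%d_r%02d", manifest$sample_id,
                                   manifest$condition, manifest$replicate)
  manifest$seed <- vapply(manifest$recording_id, function(id) {
    derive_seed(seed, paste0("recording/", id))
  }, integer(1))
  manifest[, c("recording_id", "sample_id", "condition", "replicate", "seed")]
}
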