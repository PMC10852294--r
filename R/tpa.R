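#' Segment a two-compression force curve into its cycles
#'
#' Locates the first and second compression cycles. When the probe actuation
#' timeline is available the bounds follow it directly: each cycle is a
#' contiguous run of nonzero probe penetration (descent + ascent). Without
#' actuation the split falls back to the force signal: the curve is
#' thresholded at 2% of its global maximum and the split is placed at the
#' midpoint of the longest interior sub-threshold run between the two humps.
#'
#' @param force Numeric force series (N).
#' @param actuation Optional probe-depth series (mm) aligned with `force`.
#' @param n_expected Number of compression episodes expected (default 2).
#' @return A list of two integer vectors `c(start, end)` (1-based, inclusive)
#'   bounding each cycle.
#' @export
segment_cycles <- function(force, actuation = NULL, n_expected = 2L) {
  n <- length(force)
  if (!is.null(actuation)) {
    stopifnot(length(actuation) == n)
    on <- actuation > max(actuation) * 1e-9
    r <- rle(on)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    if (length(runs) != n_expected) {
      stop("segmentation error: found ", length(runs),
           " compression episodes, expected ", n_expected, call. = FALSE)
    }
    return(lapply(runs, function(i) c(starts[i], ends[i])))
  }
  thr <- 0.02 * max(force)
  if (thr <= 0) {
    stop("segmentation error: found 0 compression episodes, expected ",
         n_expected, call. = FALSE)
  }
  above <- force > thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  humps <- which(r$values)
  if (length(humps) < n_expected) {
    stop("segmentation error: found ", length(humps),
         " compression episodes, expected ", n_expected, call. = FALSE)
  }
  # longest sub-threshold gap strictly between the first and last hump
  gaps <- which(!r$values & seq_along(r$values) > humps[1] &
                  seq_along(r$values) < humps[length(humps)])
  g <- gaps[which.max(r$lengths[gaps])]
  split <- starts[g] + (r$lengths[g] %/% 2L)
  list(c(1L, split), c(split + 1L, n))
}

#' Texture profile analysis of a two-compression force curve
#'
#' Computes the six classical double-compression TPA parameters used as
#' force features:
#' * **hardness** — maximum force during the first compression (N);
#' * **fracturability** — force at the first significant drop before the
#'   first-compression peak (a drop exceeding `drop_frac` of the cycle-1
#'   maximum); equals hardness when the curve rises monotonically to its
#'   apex (N);
#' * **adhesive_force** — magnitude of the most negative force between the
#'   end of cycle 1 and the start of cycle 2 (N, 0 if the force never goes
#'   negative there);
#' * **adhesiveness** — area of the negative force over that window
#'   (N·s, trapezoidal);
#' * **cohesiveness** — positive-force area of cycle 2 over that of cycle 1
#'   (dimensionless);
#' * **gumminess** — hardness x cohesiveness (N).
#'
#' @param force Numeric force series (N).
#' @param time_s Time stamps (s), monotone increasing.
#' @param cycle_bounds Two `c(start, end)` pairs, e.g. from
#'   [segment_cycles()].
#' @param drop_frac Fracturability drop threshold as a fraction of the
#'   cycle-1 maximum (default 0.05; must exceed sensor noise ripple).
#' @return Named numeric vector of the six TPA features, in the fixed schema
#'   order `hardness`, `fracturability`, `adhesive_force`, `adhesiveness`,
#'   `cohesiveness`, `gumminess`.
#' @export
compute_tpa <- function(force, time_s, cycle_bounds, drop_frac = 0.05) {
  stopifnot(length(force) == length(time_s), length(cycle_bounds) == 2L)
  b1 <- cycle_bounds[[1]]; b2 <- cycle_bounds[[2]]
  if (b1[1] > b1[2] || b2[1] > b2[2] || b1[2] >= b2[1] ||
      b2[2] > length(force) || b1[1] < 1) {
    stop("invalid cycle bounds", call. = FALSE)
  }
  i1 <- b1[1]:b1[2]; i2 <- b2[1]:b2[2]
  f1 <- force[i1]
  hardness <- max(f1)
  peak_i <- which.max(f1)

  # first pre-peak drop exceeding drop_frac * hardness: track the running
  # maximum; the first time force falls that far below it, report the
  # running maximum at that point.
  fracturability <- hardness
  if (peak_i > 1L) {
    pre <- f1[1:peak_i]
    runmax <- cummax(pre)
    hit <- which(runmax - pre >= drop_frac * hardness)
    if (length(hit)) fracturability <- runmax[hit[1]]
  }

  # inter-cycle window (exclusive of both cycles)
  adhesive_force <- 0
  adhesiveness <- 0
  if (b2[1] - b1[2] >= 2L) {
    iw <- (b1[2] + 1L):(b2[1] - 1L)
    fw <- force[iw]
    if (any(fw < 0)) {
      adhesive_force <- abs(min(fw))
      adhesiveness <- abs(trapz(time_s[iw], pmin(fw, 0)))
    }
  }

  a1 <- trapz(time_s[i1], pmax(f1, 0))
  a2 <- trapz(time_s[i2], pmax(force[i2], 0))
  if (a1 <= 0) {
    stop("undefined-cohesiveness: cycle-1 positive-force area is zero",
         call. = FALSE)
  }
  cohesiveness <- a2 / a1
  c(hardness = hardness,
    fracturability = fracturability,
    adhesive_force = adhesive_force,
    adhesiveness = adhesiveness,
    cohesiveness = cohesiveness,
    gumminess = hardness * cohesiveness)
}

#' Extract the six TPA features from a chew recording
#'
#' Convenience wrapper: segments the force curve using the recording's
#' actuation timeline and applies [compute_tpa()].
#'
#' @param recording A `chew_recording`.
#' @param drop_frac See [compute_tpa()].
#' @return Named numeric vector of length 6.
#' @export
extract_tpa_features <- function(recording, drop_frac = 0.05) {
  stopifnot(inherits(recording, "chew_recording"))
  bounds <- segment_cycles(recording$force, recording$actuation)
  time_s <- (seq_along(recording$force) - 1L) / recording$force_fs_Hz
  compute_tpa(recording$force, time_s, bounds, drop_frac = drop_frac)
}
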