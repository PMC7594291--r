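#' Draw random deposition endpoints from a trajectory
#'
#' Samples `n` endpoints uniformly at random, with replacement, from the
#' recorded GPS fixes of one individual. Endpoints are candidate seed
#' deposition sites; each carries its fix timestamp and position.
#'
#' @param traj A `deer_trajectory` (see [filter_and_split()]).
#' @param n Number of draws (>= 1).
#' @return Data frame with columns `timestamp`, `easting`, `northing`,
#'   `elevation`, one row per draw.
#' @export
sample_endpoints <- function(traj, n) {
  if (nrow(traj) < 2L) stop("trajectory must have at least 2 fixes")
  stopifnot(n >= 1)
  idx <- sample.int(nrow(traj), n, replace = TRUE)
  out <- as.data.frame(traj)[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Locate the dispersal start position on a trajectory
#'
#' Given simulated start times (endpoint time minus gut passage time),
#' returns the position on the individual's movement trajectory at each
#' time. With `rule = "interpolate"` (default) easting, northing and
#' elevation are linearly interpolated between the bracketing fixes; an
#' exact fix hit returns that fix. With `rule = "nearest"` the position
#' snaps to the fix nearest in time. Start times before the first fix (and,
#' defensively, after the last) are unresolved: the caller redraws or drops
#' them.
#'
#' @param traj A `deer_trajectory`.
#' @param t_start POSIXct vector of start times.
#' @param rule `"interpolate"` or `"nearest"`.
#' @return Data frame with columns `easting`, `northing`, `elevation` and
#'   logical `resolved`; position columns are `NA` where unresolved.
#' @export
locate_start <- function(traj, t_start, rule = c("interpolate", "nearest")) {
  rule <- match.arg(rule)
  ts <- as.numeric(traj$timestamp)
  t <- as.numeric(t_start)
  n <- length(ts)
  resolved <- t >= ts[1] & t <= ts[n]
  e <- z <- no <- rep(NA_real_, length(t))
  if (any(resolved)) {
    tt <- t[resolved]
    if (rule == "nearest") {
      i <- findInterval(tt, ts, all.inside = TRUE)
      snap_up <- (tt - ts[i]) > (ts[i + 1L] - tt)
      i <- i + as.integer(snap_up)
      e[resolved] <- traj$easting[i]
      no[resolved] <- traj$northing[i]
      z[resolved] <- traj$elevation[i]
    } else {
      i <- findInterval(tt, ts, all.inside = TRUE)
      w <- (tt - ts[i]) / (ts[i + 1L] - ts[i])
      e[resolved] <- (1 - w) * traj$easting[i] + w * traj$easting[i + 1L]
      no[resolved] <- (1 - w) * traj$northing[i] + w * traj$northing[i + 1L]
      z[resolved] <- (1 - w) * traj$elevation[i] + w * traj$elevation[i + 1L]
    }
  }
  data.frame(easting = e, northing = no, elevation = z, resolved = resolved)
}

#' Simulate per-seed dispersal events for one individual
#'
#' The mechanistic core, implementing d = v * p: each event draws a random
#' deposition endpoint from the trajectory's fixes and a gut passage time p
#' from the pooled passage-time sample; the dispersal start time is the
#' endpoint time minus p and the start position is located on the trajectory
#' (see [locate_start()]). Horizontal displacement is the planar Euclidean
#' distance between start and end, vertical displacement the signed
#' elevation difference (end minus start). Events whose start time falls
#' before the trajectory begins are redrawn (endpoint and p together) up to
#' `cfg$max_redraws` times, then dropped; the dropped fraction is recorded.
#'
#' In exhaustive mode every (fix, p) pair is enumerated exactly once with no
#' redraws (unresolved pairs are dropped), which makes small cases exactly
#' checkable against brute-force enumeration.
#'
#' @param traj A `deer_trajectory`.
#' @param p_samples Numeric vector of passage times in hours (non-empty).
#' @param cfg A [dispersal_config()].
#' @param exhaustive If `TRUE`, enumerate all fix x p pairs instead of
#'   drawing `cfg$n_endpoint_draws` random events.
#' @return Data frame of dispersal events with columns `animal_id`, `month`
#'   (endpoint calendar month, UTC), `passage_h`, `start_e`, `start_n`,
#'   `start_z`, `end_e`, `end_n`, `end_z`, `d_horiz_m`, `d_vert_m`, plus
#'   attributes `n_attempted` and `dropped_fraction`.
#' @export
simulate_events <- function(traj, p_samples, cfg = dispersal_config(),
                            exhaustive = FALSE) {
  if (length(p_samples) == 0L) stop("p_samples must be non-empty")
  if (nrow(traj) < 2L) stop("trajectory must have at least 2 fixes")
  animal <- attr(traj, "animal_id")
  if (is.null(animal)) animal <- "unknown"

  if (exhaustive) {
    grid <- expand.grid(fix = seq_len(nrow(traj)),
                        p = unique(p_samples), KEEP.OUT.ATTRS = FALSE)
    end <- as.data.frame(traj)[grid$fix, , drop = FALSE]
    p <- grid$p
  } else {
    n <- cfg$n_endpoint_draws
    end <- sample_endpoints(traj, n)
    p <- p_samples[sample.int(length(p_samples), n, replace = TRUE)]
  }
  n_attempted <- length(p)
  t_start <- end$timestamp - p * 3600
  start <- locate_start(traj, t_start, rule = cfg$start_rule)

  if (!exhaustive && cfg$max_redraws > 0L) {
    for (round in seq_len(cfg$max_redraws)) {
      bad <- which(!start$resolved)
      if (!length(bad)) break
      redraw_end <- sample_endpoints(traj, length(bad))
      redraw_p <- p_samples[sample.int(length(p_samples), length(bad),
                                       replace = TRUE)]
      end[bad, ] <- redraw_end
      p[bad] <- redraw_p
      start[bad, ] <- locate_start(traj, redraw_end$timestamp -
                                     redraw_p * 3600, rule = cfg$start_rule)
    }
  }
  keep <- start$resolved
  dropped <- 1 - mean(keep)
  if (!any(keep)) {
    stop("all simulated events for animal ", animal, " were dropped; ",
         "the trajectory is too short for the passage-time support")
  }
  end <- end[keep, , drop = FALSE]
  start <- start[keep, , drop = FALSE]
  p <- p[keep]

  ev <- data.frame(
    animal_id = animal,
    month = month_label(end$timestamp),
    passage_h = p,
    start_e = start$easting, start_n = start$northing,
    start_z = start$elevation,
    end_e = end$easting, end_n = end$northing, end_z = end$elevation
  )
  ev$d_horiz_m <- sqrt((ev$end_e - ev$start_e)^2 + (ev$end_n - ev$start_n)^2)
  ev$d_vert_m <- ev$end_z - ev$start_z
  rownames(ev) <- NULL
  attr(ev, "n_attempted") <- n_attempted
  attr(ev, "dropped_fraction") <- dropped
  ev
}

#' Simulate dispersal events for a whole population
#'
#' Runs [simulate_events()] for each trajectory and pools the results. The
#' draw budget (`cfg$n_endpoint_draws`) is per individual; months are
#' stratified post hoc by each event's endpoint month.
#'
#' @param trajectories Named list of `deer_trajectory` objects.
#' @param p_samples Pooled passage-time sample in hours.
#' @param cfg A [dispersal_config()].
#' @return Pooled event data frame; attribute `dropped_fractions` is a named
#'   vector of per-individual dropped fractions.
#' @export
simulate_all_events <- function(trajectories, p_samples,
                                cfg = dispersal_config()) {
  stopifnot(length(trajectories) >= 1L)
  evs <- lapply(trajectories, simulate_events, p_samples = p_samples,
                cfg = cfg)
  dropped <- vapply(evs, attr, numeric(1), which = "dropped_fraction")
  out <- do.call(rbind, c(evs, list(make.row.names = FALSE)))
  attr(out, "dropped_fractions") <- dropped
  out
}

#' Per-cell long-distance dispersal probabilities
#'
#' Aggregates dispersal events to the (individual, month) cell grain and
#' computes, per cell, the per-seed LDD probability in three orientations:
#' `horizontal` is the fraction of events with horizontal displacement
#' strictly beyond the horizontal threshold (default 1000 m), `upward` the
#' fraction with vertical displacement above the vertical threshold (default
#' 50 m), and `downward` the fraction below minus that threshold.
#'
#' @param events Event data frame from [simulate_events()] or
#'   [simulate_all_events()].
#' @param cfg A [dispersal_config()] providing the thresholds.
#' @return Long data frame (class `ldd_table`) with columns `animal_id`,
#'   `month`, `orientation`, `prob`, `n_events`.
#' @export
ldd_probability_table <- function(events, cfg = dispersal_config()) {
  if (nrow(events) == 0L) stop("events must be non-empty")
  key <- interaction(events$animal_id, events$month, drop = TRUE, sep = "\r")
  agg <- function(x) tapply(x, key, mean)
  h <- agg(events$d_horiz_m > cfg$horizontal_threshold)
  up <- agg(events$d_vert_m > cfg$vertical_threshold)
  dn <- agg(events$d_vert_m < -cfg$vertical_threshold)
  n <- as.vector(table(key))
  parts <- strsplit(names(h), "\r", fixed = TRUE)
  animal <- vapply(parts, `[`, character(1), 1L)
  mon <- vapply(parts, `[`, character(1), 2L)
  out <- data.frame(
    animal_id = rep(animal, 3L),
    month = factor(rep(mon, 3L), levels = MONTH_LEVELS, ordered = TRUE),
    orientation = rep(c("horizontal", "upward", "downward"), each = length(h)),
    prob = c(as.vector(h), as.vector(up), as.vector(dn)),
    n_events = rep(n, 3L)
  )
  out <- out[order(out$orientation, out$animal_id, out$month), ]
  rownames(out) <- NULL
  class(out) <- c("ldd_table", "data.frame")
  out
}

#' Pooled dispersal-kernel summary
#'
#' Summarises the pooled distribution of simulated dispersal distances:
#' mean horizontal displacement, the fractions of events beyond the
#' horizontal threshold and beyond the vertical threshold upward and
#' downward, and the 1%/99% quantiles of horizontal and vertical
#' displacement.
#'
#' @param events Non-empty event data frame.
#' @param cfg A [dispersal_config()] providing the thresholds.
#' @return Named list with `n_events`, `mean_horizontal_m`,
#'   `frac_horizontal_ldd`, `frac_upward_ldd`, `frac_downward_ldd`,
#'   `q01_horizontal_m`, `q99_horizontal_m`, `q01_vertical_m`,
#'   `q99_vertical_m`.
#' @export
kernel_summary <- function(events, cfg = dispersal_config()) {
  if (nrow(events) == 0L) stop("events must be non-empty")
  qh <- empirical_quantiles(events$d_horiz_m, c(0.01, 0.99))
  qv <- empirical_quantiles(events$d_vert_m, c(0.01, 0.99))
  list(
    n_events = nrow(events),
    mean_horizontal_m = mean(events$d_horiz_m),
    frac_horizontal_ldd = mean(events$d_horiz_m > cfg$horizontal_threshold),
    frac_upward_ldd = mean(events$d_vert_m > cfg$vertical_threshold),
    frac_downward_ldd = mean(events$d_vert_m < -cfg$vertical_threshold),
    q01_horizontal_m = qh[1], q99_horizontal_m = qh[2],
    q01_vertical_m = qv[1], q99_vertical_m = qv[2]
  )
}
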