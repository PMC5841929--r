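# Position cleaning, smoothing, velocity and lap segmentation.

#' Construct a position trace
#'
#' A position trace holds diode-tracking samples for one session: time in
#' seconds (strictly increasing), head position in cm, and a per-sample
#' validity flag (FALSE marks tracking artifacts, e.g. obscured diodes).
#'
#' @param t numeric, sample times in seconds, strictly increasing.
#' @param x,y numeric, position in cm.
#' @param valid logical, per-sample validity (default all TRUE).
#' @return a `position_trace`: a data.frame with columns `t`, `x`, `y`,
#'   `valid`.
#' @export
position_trace <- function(t, x, y = rep(0, length(t)), valid = rep(TRUE, length(t))) {
  stopifnot(length(t) == length(x), length(t) == length(y),
            length(t) == length(valid))
  if (any(diff(t) <= 0)) stop("position times must be strictly increasing")
  structure(data.frame(t = as.numeric(t), x = as.numeric(x),
                       y = as.numeric(y), valid = as.logical(valid)),
            class = c("position_trace", "data.frame"))
}

#' Remove tracking artifacts from a position trace
#'
#' Samples implying an instantaneous speed above `max_speed_cm_s` relative
#' to the last accepted sample are flagged invalid, as are samples already
#' flagged on input; flagged samples are replaced by linear interpolation
#' between the surrounding valid samples (constant extrapolation at the
#' edges). The number of repaired samples is attached as attribute
#' `n_repaired`.
#'
#' @param p a [position_trace()].
#' @param max_speed_cm_s jump threshold; implied speeds above it are
#'   treated as artifacts. Default 150 cm/s, far above rodent top speed.
#' @return cleaned `position_trace` (all samples valid).
#' @export
clean_positions <- function(p, max_speed_cm_s = 150) {
  n <- nrow(p)
  if (sum(p$valid) < 2L) stop("need at least 2 valid position samples")
  bad <- !p$valid
  last <- which(p$valid)[1L]          # first valid anchors the walk
  for (i in seq_len(n)[-seq_len(which(p$valid)[1L])]) {
    if (bad[i]) next
    dt <- p$t[i] - p$t[last]
    v <- sqrt((p$x[i] - p$x[last])^2 + (p$y[i] - p$y[last])^2) / dt
    if (v > max_speed_cm_s) bad[i] <- TRUE else last <- i
  }
  if (all(bad)) stop("no valid samples survive artifact removal")
  out <- p
  if (any(bad)) {
    ok <- !bad
    out$x <- stats::approx(p$t[ok], p$x[ok], xout = p$t, rule = 2)$y
    out$y <- stats::approx(p$t[ok], p$y[ok], xout = p$t, rule = 2)$y
  }
  out$valid <- TRUE
  attr(out, "n_repaired") <- sum(bad & p$valid) + sum(!p$valid)
  out
}

#' Smooth a position trace with a Gaussian kernel
#'
#' Gaussian smoothing of `x` and `y` with a kernel of standard deviation
#' `sd_s` seconds; requires uniform sampling; reflective edge handling.
#'
#' @param p a cleaned [position_trace()].
#' @param sd_s kernel SD in seconds (default 0.05 s).
#' @return smoothed `position_trace`.
#' @export
smooth_positions <- function(p, sd_s = 0.05) {
  dt <- diff(p$t)
  if (length(dt) < 1L) stop("need at least 2 samples")
  if (diff(range(dt)) > 1e-6 * stats::median(dt) + 1e-9)
    stop("smooth_positions requires uniform sampling; clean/resample first")
  sd_samp <- sd_s / stats::median(dt)
  out <- p
  out$x <- gauss_smooth(p$x, sd_samp)
  out$y <- gauss_smooth(p$y, sd_samp)
  out
}

#' Compute smoothed running speed from a position trace
#'
#' Speed is the Euclidean displacement per time step (assigned to the
#' right sample, first sample duplicated), then Gaussian-smoothed with a
#' kernel of `smooth_sd_samples` samples.
#'
#' @param p a [position_trace()].
#' @param smooth_sd_samples kernel SD in samples (default 2.5).
#' @return a `velocity_trace`: data.frame with `t` (s) and `speed` (cm/s).
#' @export
compute_velocity <- function(p, smooth_sd_samples = 2.5) {
  if (nrow(p) < 2L) stop("need at least 2 samples")
  dt <- diff(p$t)
  if (any(dt == 0)) stop("duplicate timestamps in position trace")
  v <- sqrt(diff(p$x)^2 + diff(p$y)^2) / dt
  v <- c(v[1L], v)
  v <- pmax(0, gauss_smooth(v, smooth_sd_samples))
  structure(data.frame(t = p$t, speed = v),
            class = c("velocity_trace", "data.frame"))
}

#' Project positions onto the principal track axis
#'
#' Collapses the 2D trace to a 1D coordinate by projecting onto the first
#' principal axis of (x, y) and shifting so the minimum is 0. For a linear
#' track this recovers position along the track.
#'
#' @param p a [position_trace()].
#' @return numeric vector of 1D positions in cm, one per sample.
#' @export
linearize_positions <- function(p) {
  xy <- cbind(p$x, p$y)
  ctr <- colMeans(xy)
  sv <- svd(sweep(xy, 2, ctr))
  ax <- sv$v[, 1L]
  if (ax[which.max(abs(ax))] < 0) ax <- -ax   # orient along dominant coordinate
  u <- as.numeric(sweep(xy, 2, ctr) %*% ax)
  u - min(u)
}

#' Segment a linear-track session into directional laps
#'
#' A lap is a traversal from one track-end zone (the outer
#' `end_zone_frac` of the track) to the other. The lap starts at the last
#' sample inside the origin end zone and ends at the first sample inside
#' the destination zone, so brief mid-track reversals that do not re-enter
#' an end zone still count as one lap. Excursions that return to the same
#' end are discarded.
#'
#' @param p a [position_trace()]; positions are linearized internally.
#' @param track_length_cm track length; default the range of the
#'   linearized coordinate.
#' @param end_zone_frac fraction of the track at each end forming the
#'   turnaround zones (default 0.1).
#' @return data.frame with columns `direction` ("left"/"right"),
#'   `t_start`, `t_end`, `x_start`, `x_end`; zero rows if no complete
#'   traversal.
#' @export
detect_laps <- function(p, track_length_cm = NULL, end_zone_frac = 0.1) {
  u <- linearize_positions(p)
  L <- if (is.null(track_length_cm)) max(u) else track_length_cm
  lo <- u <= end_zone_frac * L
  hi <- u >= (1 - end_zone_frac) * L
  zone <- ifelse(lo, -1L, ifelse(hi, 1L, 0L))
  laps <- list()
  cur <- 0L            # zone we last occupied
  i_exit <- NA_integer_  # last sample index inside that zone
  for (i in seq_along(zone)) {
    z <- zone[i]
    if (z == 0L) next
    if (cur == 0L || z == cur) {
      cur <- z
      i_exit <- i
    } else {
      # entered the opposite zone: a traversal completed
      laps[[length(laps) + 1L]] <- data.frame(
        direction = if (z > cur) "right" else "left",
        t_start = p$t[i_exit], t_end = p$t[i],
        x_start = u[i_exit], x_end = u[i])
      cur <- z
      i_exit <- i
    }
  }
  if (!length(laps))
    return(data.frame(direction = character(), t_start = numeric(),
                      t_end = numeric(), x_start = numeric(),
                      x_end = numeric()))
  do.call(rbind, laps)
}
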