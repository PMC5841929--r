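# Rate maps, directional rate curves, place fields and spatial metrics.

#' Occupancy-normalized firing rate map (1D, along the track axis)
#'
#' Positions are linearized onto the principal track axis and binned at
#' `bin_cm`. Occupancy time and spike counts are accumulated only for
#' samples/spikes where running speed is at least `vmin` cm/s; unvisited
#' bins are flagged and excluded from all summaries. Two smoothing orders
#' are available: `"divide-then-smooth"` (rate = counts/occupancy, then
#' Gaussian smoothing of the rate map over visited bins; the default) and
#' `"smooth-then-divide"` (spike-count and occupancy maps smoothed
#' separately before division).
#'
#' @param spikes a [spike_train()] (or numeric vector of spike times, s).
#' @param pos a [position_trace()] covering the run epoch.
#' @param vel a [compute_velocity()] trace aligned to `pos`.
#' @param bin_cm spatial bin size, cm (default 1).
#' @param smooth_sd_bins Gaussian smoothing SD in bins (default 1).
#' @param vmin running-speed threshold, cm/s (default 2).
#' @param track_length_cm track length; default from the data.
#' @param smooth_mode `"divide-then-smooth"` or `"smooth-then-divide"`.
#' @return object of class `rate_map`: list with `bin_size_cm`,
#'   `bin_centers` (cm), `rate` (smoothed Hz, `NA` at unvisited bins),
#'   `n_spikes` and `occ_time_s` per bin (raw), `p_occ` (occupancy
#'   probability over visited bins, sums to 1), `visited`, `mean_rate`
#'   (run-epoch spikes / run-epoch time), `peak_rate`, and the smoothing
#'   settings.
#' @export
compute_rate_map <- function(spikes, pos, vel, bin_cm = 1,
                             smooth_sd_bins = 1, vmin = 2,
                             track_length_cm = NULL,
                             smooth_mode = c("divide-then-smooth",
                                             "smooth-then-divide")) {
  smooth_mode <- match.arg(smooth_mode)
  st <- if (inherits(spikes, "spike_train")) spikes$t else as.numeric(spikes)
  u <- linearize_positions(pos)
  L <- if (is.null(track_length_cm)) max(u) else track_length_cm
  nb <- max(1L, ceiling(L / bin_cm))
  breaks <- seq(0, nb * bin_cm, by = bin_cm)
  dt <- stats::median(diff(pos$t))
  run <- vel$speed >= vmin
  if (!any(run)) stop("zero occupancy above the speed threshold")
  occ <- graphics::hist(pmin(u[run], L - 1e-9), breaks = breaks,
                        plot = FALSE)$counts * dt
  keep <- st >= pos$t[1] & st <= pos$t[nrow(pos)]
  st <- st[keep]
  sx <- stats::approx(pos$t, u, xout = st)$y
  sv <- stats::approx(vel$t, vel$speed, xout = st)$y
  sx <- sx[sv >= vmin]
  cnt <- graphics::hist(pmin(sx, L - 1e-9), breaks = breaks,
                        plot = FALSE)$counts
  visited <- occ > 0
  if (smooth_mode == "divide-then-smooth") {
    raw <- ifelse(visited, cnt / occ, NA_real_)
    rate <- gauss_smooth(raw, smooth_sd_bins)
  } else {
    cs <- gauss_smooth(ifelse(visited, cnt, NA_real_), smooth_sd_bins)
    os <- gauss_smooth(ifelse(visited, occ, NA_real_), smooth_sd_bins)
    rate <- ifelse(visited & os > 0, cs / os, NA_real_)
  }
  structure(list(
    bin_size_cm = bin_cm,
    bin_centers = breaks[-1] - bin_cm / 2,
    rate = rate,
    n_spikes = cnt,
    occ_time_s = occ,
    p_occ = occ / sum(occ),
    visited = visited,
    mean_rate = sum(cnt) / sum(occ),
    peak_rate = if (any(visited)) max(rate[visited]) else NA_real_,
    smooth_sd_bins = smooth_sd_bins,
    smooth_mode = smooth_mode,
    vmin = vmin), class = "rate_map")
}

#' @export
print.rate_map <- function(x, ...) {
  cat(sprintf("<rate_map> %d x %.0f cm bins, peak %.2f Hz, mean %.2f Hz, %d unvisited\n",
              length(x$rate), x$bin_size_cm, x$peak_rate, x$mean_rate,
              sum(!x$visited)))
  invisible(x)
}

#' Directional firing rate curves (left and right laps)
#'
#' For each running direction, the firing curve is the total number of
#' spikes fired across all laps of that direction in each spatial bin,
#' divided by the total time spent in that bin during those laps.
#' `fr_mean` is the direction-mean firing rate (all spikes in those laps
#' over the summed lap time), the quantity entering the directionality
#' index.
#'
#' @param spikes a [spike_train()] or numeric spike times.
#' @param pos,laps a [position_trace()] and [detect_laps()] table.
#' @param bin_cm,smooth_sd_bins,track_length_cm,smooth_mode as in
#'   [compute_rate_map()].
#' @return list with components `left` and `right`, each a `rate_map`
#'   restricted to that direction's laps with an extra `fr_mean` field,
#'   plus `bin_centers`.
#' @export
compute_rate_curves <- function(spikes, pos, laps, bin_cm = 1,
                                smooth_sd_bins = 1, track_length_cm = NULL,
                                smooth_mode = "divide-then-smooth") {
  st <- if (inherits(spikes, "spike_train")) spikes$t else as.numeric(spikes)
  u <- linearize_positions(pos)
  L <- if (is.null(track_length_cm)) max(u) else track_length_cm
  nb <- max(1L, ceiling(L / bin_cm))
  breaks <- seq(0, nb * bin_cm, by = bin_cm)
  dt <- stats::median(diff(pos$t))
  one_dir <- function(dir) {
    lp <- laps[laps$direction == dir, , drop = FALSE]
    in_lap <- rep(FALSE, nrow(pos))
    sp_in <- rep(FALSE, length(st))
    for (k in seq_len(nrow(lp))) {
      in_lap <- in_lap | (pos$t >= lp$t_start[k] & pos$t < lp$t_end[k])
      sp_in <- sp_in | (st >= lp$t_start[k] & st < lp$t_end[k])
    }
    occ <- graphics::hist(pmin(u[in_lap], L - 1e-9), breaks = breaks,
                          plot = FALSE)$counts * dt
    sx <- stats::approx(pos$t, u, xout = st[sp_in])$y
    cnt <- graphics::hist(pmin(sx, L - 1e-9), breaks = breaks,
                          plot = FALSE)$counts
    visited <- occ > 0
    raw <- ifelse(visited, cnt / occ, NA_real_)
    rate <- if (smooth_mode == "divide-then-smooth")
      gauss_smooth(raw, smooth_sd_bins)
    else {
      cs <- gauss_smooth(ifelse(visited, cnt, NA_real_), smooth_sd_bins)
      os <- gauss_smooth(ifelse(visited, occ, NA_real_), smooth_sd_bins)
      ifelse(visited & os > 0, cs / os, NA_real_)
    }
    structure(list(bin_size_cm = bin_cm, bin_centers = breaks[-1] - bin_cm / 2,
                   rate = rate, n_spikes = cnt, occ_time_s = occ,
                   p_occ = if (sum(occ) > 0) occ / sum(occ) else occ,
                   visited = visited,
                   mean_rate = if (sum(occ) > 0) sum(cnt) / sum(occ) else NA_real_,
                   peak_rate = if (any(visited)) max(rate[visited]) else NA_real_,
                   fr_mean = if (sum(occ) > 0) sum(cnt) / sum(occ) else NA_real_,
                   smooth_sd_bins = smooth_sd_bins, smooth_mode = smooth_mode),
              class = "rate_map")
  }
  list(left = one_dir("left"), right = one_dir("right"),
       bin_centers = breaks[-1] - bin_cm / 2)
}

#' Detect place fields in a rate map
#'
#' The main place field is the maximal set of contiguous visited bins
#' containing the global peak in which the (smoothed) rate exceeds
#' `frac_peak` (default 20%) of the peak rate. Additional fields are
#' found by repeating the rule on the remaining bins while local peaks
#' exceed `min_peak_rate`. The unit is flagged a place cell when the main
#' field spans at least `min_size_bins` bins, the map mean rate exceeds
#' `min_mean_rate`, the peak exceeds `min_peak_rate`, and the
#' signal-to-noise ratio — defined as log2(in-field rate / out-field
#' rate) — is positive. In-/out-field rates are raw spike counts inside /
#' outside the main field divided by the time spent there.
#'
#' @param map a [compute_rate_map()] object.
#' @param frac_peak field boundary as a fraction of the field peak.
#' @param min_size_bins,min_mean_rate,min_peak_rate place-cell criteria
#'   (defaults 6 bins, 0.2 Hz, 1.0 Hz).
#' @return list with `fields` (data.frame: `start_bin`, `end_bin`,
#'   `size_bins`, `peak_rate`, `peak_bin`), `main_field` (row index or
#'   NA), `infield_rate`, `outfield_rate`, `snr`, `is_place_cell`.
#' @export
detect_place_fields <- function(map, frac_peak = 0.2, min_size_bins = 6,
                                min_mean_rate = 0.2, min_peak_rate = 1.0) {
  r <- map$rate
  r[!map$visited] <- NA_real_
  avail <- !is.na(r)
  fields <- list()
  while (any(avail) && max(r[avail]) > min_peak_rate) {
    pk <- which(avail)[which.max(r[avail])]
    thr <- frac_peak * r[pk]
    lo <- pk
    while (lo > 1L && avail[lo - 1L] && !is.na(r[lo - 1L]) && r[lo - 1L] > thr)
      lo <- lo - 1L
    hi <- pk
    while (hi < length(r) && avail[hi + 1L] && !is.na(r[hi + 1L]) &&
           r[hi + 1L] > thr) hi <- hi + 1L
    fields[[length(fields) + 1L]] <- data.frame(
      start_bin = lo, end_bin = hi, size_bins = hi - lo + 1L,
      peak_rate = r[pk], peak_bin = pk)
    avail[lo:hi] <- FALSE
  }
  if (!length(fields)) {
    return(list(fields = data.frame(start_bin = integer(), end_bin = integer(),
                                    size_bins = integer(), peak_rate = numeric(),
                                    peak_bin = integer()),
                main_field = NA_integer_, infield_rate = NA_real_,
                outfield_rate = NA_real_, snr = NA_real_,
                is_place_cell = FALSE))
  }
  fdf <- do.call(rbind, fields)
  main <- which.max(fdf$peak_rate)
  inb <- fdf$start_bin[main]:fdf$end_bin[main]
  in_t <- sum(map$occ_time_s[inb])
  out_idx <- setdiff(which(map$visited), inb)
  out_t <- sum(map$occ_time_s[out_idx])
  infield <- if (in_t > 0) sum(map$n_spikes[inb]) / in_t else NA_real_
  outfield <- if (out_t > 0) sum(map$n_spikes[out_idx]) / out_t else NA_real_
  snr <- if (!is.na(infield) && !is.na(outfield)) {
    if (outfield == 0) ifelse(infield > 0, Inf, NA_real_)
    else log2(infield / outfield)
  } else NA_real_
  list(fields = fdf, main_field = main,
       infield_rate = infield, outfield_rate = outfield, snr = snr,
       is_place_cell = fdf$size_bins[main] >= min_size_bins &&
         map$mean_rate > min_mean_rate &&
         fdf$peak_rate[main] > min_peak_rate &&
         isTRUE(snr > 0))
}

#' Spatial information rate (bits per second)
#'
#' The Skaggs information rate: SI = sum_i p_i * lambda_i *
#' log2(lambda_i / lambda_bar), over visited bins, where p_i is the
#' occupancy probability, lambda_i the bin firing rate and lambda_bar the
#' occupancy-weighted mean rate. Bins with zero rate contribute zero; a
#' silent map has SI = 0.
#'
#' @param map a [compute_rate_map()] object.
#' @return nonnegative scalar, bits/s.
#' @export
spatial_information <- function(map) {
  i <- which(map$visited & !is.na(map$rate))
  p <- map$p_occ[i]
  lam <- map$rate[i]
  lbar <- sum(p * lam)
  if (lbar <= 0) return(0)
  pos <- lam > 0
  sum(p[pos] * lam[pos] * log2(lam[pos] / lbar))
}

#' Firing rate map sparsity
#'
#' sparsity = 1 - (sum p_i lambda_i)^2 / (sum p_i lambda_i^2), in
#' \[0, 1\]: 0 for a map with equal rate in every visited bin, approaching
#' 1 when all spikes fall in a single bin.
#'
#' @param map a [compute_rate_map()] object.
#' @return scalar in \[0, 1\]; `NA` with a warning for a silent map.
#' @export
map_sparsity <- function(map) {
  i <- which(map$visited & !is.na(map$rate))
  p <- map$p_occ[i]
  lam <- map$rate[i]
  m2 <- sum(p * lam^2)
  if (m2 <= 0) {
    warning("sparsity undefined for a silent map")
    return(NA_real_)
  }
  1 - sum(p * lam)^2 / m2
}

#' Directionality index of a place cell
#'
#' DI = |FR_lm - FR_rm| / (FR_lm + FR_rm), where FR_lm and FR_rm are the
#' mean firing rates across all left and all right laps. Defined for
#' place cells whose main field lies in the middle 80% of the track.
#'
#' @param fr_lm,fr_rm direction-mean firing rates, Hz.
#' @return scalar in \[0, 1\]; `NA` with a warning if both rates are zero.
#' @export
directionality_index <- function(fr_lm, fr_rm) {
  if (is.na(fr_lm) || is.na(fr_rm) || fr_lm + fr_rm <= 0) {
    warning("directionality index undefined: zero rate in both directions")
    return(NA_real_)
  }
  abs((fr_lm - fr_rm) / (fr_lm + fr_rm))
}

#' Whether a field's peak lies in the middle portion of the track
#' @keywords internal
field_in_middle <- function(map, fields, middle_frac = 0.8) {
  if (is.na(fields$main_field)) return(FALSE)
  pk <- map$bin_centers[fields$fields$peak_bin[fields$main_field]]
  L <- length(map$rate) * map$bin_size_cm
  pk > (1 - middle_frac) / 2 * L && pk < (1 + middle_frac) / 2 * L
}

#' Per-cell firing-rate summaries
#'
#' Peak rate (maximal smoothed bin rate), mean rate (run-epoch spikes
#' over run-epoch time, i.e. periods with speed above the threshold used
#' for the map), and the in-/out-field rates of the main place field.
#'
#' @param map a [compute_rate_map()] object.
#' @param fields a [detect_place_fields()] result for the same map.
#' @return one-row data.frame: `peak_rate`, `mean_rate`, `infield_rate`,
#'   `outfield_rate`.
#' @export
rate_summaries <- function(map, fields) {
  data.frame(peak_rate = map$peak_rate, mean_rate = map$mean_rate,
             infield_rate = fields$infield_rate,
             outfield_rate = fields$outfield_rate)
}

#' Full spatial-metrics row for one unit
#'
#' Convenience wrapper running [compute_rate_map()],
#' [detect_place_fields()], [spatial_information()], [map_sparsity()],
#' [compute_rate_curves()] and [directionality_index()] and returning the
#' per-cell table row mirrored in the session report. The directionality
#' index is reported only for place cells whose main field peak lies in
#' the middle 80% of the track.
#'
#' @param spikes,pos,vel,laps session components.
#' @param ... parameters forwarded to [compute_rate_map()].
#' @return one-row data.frame.
#' @export
spatial_metrics <- function(spikes, pos, vel, laps, ...) {
  map <- compute_rate_map(spikes, pos, vel, ...)
  fl <- detect_place_fields(map)
  curves <- compute_rate_curves(spikes, pos, laps,
                                bin_cm = map$bin_size_cm,
                                smooth_sd_bins = map$smooth_sd_bins,
                                track_length_cm = length(map$rate) * map$bin_size_cm,
                                smooth_mode = map$smooth_mode)
  di <- if (fl$is_place_cell && field_in_middle(map, fl))
    suppressWarnings(directionality_index(curves$left$fr_mean,
                                          curves$right$fr_mean))
  else NA_real_
  data.frame(
    unit_id = if (inherits(spikes, "spike_train")) as.character(spikes$unit_id)
              else NA_character_,
    peak_rate = map$peak_rate, mean_rate = map$mean_rate,
    infield_rate = fl$infield_rate, outfield_rate = fl$outfield_rate,
    field_size_bins = if (!is.na(fl$main_field))
      fl$fields$size_bins[fl$main_field] else NA_integer_,
    field_center_cm = if (!is.na(fl$main_field))
      map$bin_centers[fl$fields$peak_bin[fl$main_field]] else NA_real_,
    si_bits_per_s = spatial_information(map),
    sparsity = suppressWarnings(map_sparsity(map)),
    di = di, is_place_cell = fl$is_place_cell,
    stringsAsFactors = FALSE)
}
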