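# Sharp-wave-ripple detection with MUA gating, and ripple metrics.

#' Default ripple detection parameters
#'
#' Band-pass 80-250 Hz with a 69th-order Kaiser-window FIR applied with
#' zero phase shift; envelope = Gaussian-smoothed magnitude of the
#' analytic (Hilbert) signal, total smoothing window 50 ms (kernel SD =
#' window/6); candidate events exceed mean + `threshold_sd` * SD of the
#' envelope for more than `min_dur_ms`, with edges extended to where the
#' envelope returns to the mean; events not coincident with a multi-unit
#' activity burst are discarded when `mua_gate` is TRUE.
#'
#' @param band,fir_order,kaiser_beta band-pass settings.
#' @param env_smooth_ms total Gaussian smoothing window, ms.
#' @param threshold_sd detection threshold in envelope SD units.
#' @param min_dur_ms minimum above-threshold core duration, ms.
#' @param mua_gate logical; require a coincident MUA burst.
#' @param mua_bin_ms,mua_smooth_sd_ms MUA instantaneous-rate settings.
#' @return named list of parameters.
#' @export
ripple_params <- function(band = c(80, 250), fir_order = 69, kaiser_beta = 5,
                          env_smooth_ms = 50, threshold_sd = 3,
                          min_dur_ms = 30, mua_gate = TRUE,
                          mua_bin_ms = 1, mua_smooth_sd_ms = 5) {
  stopifnot(threshold_sd > 0, min_dur_ms > 0, band[1] < band[2])
  list(band = band, fir_order = fir_order, kaiser_beta = kaiser_beta,
       env_smooth_ms = env_smooth_ms, threshold_sd = threshold_sd,
       min_dur_ms = min_dur_ms, mua_gate = mua_gate,
       mua_bin_ms = mua_bin_ms, mua_smooth_sd_ms = mua_smooth_sd_ms)
}

#' Ripple-band envelope of an LFP epoch
#'
#' @param lfp an [lfp_signal()] restricted to the rest epoch.
#' @param params a [ripple_params()] list.
#' @return object of class `ripple_envelope`: list with `env`, `mean`,
#'   `sd` (over the whole epoch), `filtered`, `t`, `fs_hz`.
#' @export
ripple_envelope <- function(lfp, params = ripple_params()) {
  fs <- lfp$fs_hz
  ntaps <- params$fir_order + 1L
  if (length(lfp$samples) < 10L * ntaps)
    stop("epoch shorter than 10 filter lengths")
  taps <- fir_design(params$fir_order, params$band, fs, params$kaiser_beta)
  f <- filt_zerophase(lfp$samples, taps)
  env <- Mod(analytic_signal(f))
  sd_samp <- params$env_smooth_ms / 6 * fs / 1000
  env <- gauss_smooth(env, sd_samp)
  structure(list(env = env, mean = mean(env), sd = stats::sd(env),
                 filtered = f, t = lfp_times(lfp), fs_hz = fs),
            class = "ripple_envelope")
}

#' Detect threshold crossings with return-to-baseline edges
#'
#' Shared event rule for the LFP envelope and the MUA rate: maximal
#' intervals above `mean + threshold_sd * sd` lasting more than
#' `min_dur_ms` become event cores; each core is extended bidirectionally
#' to the nearest sample at or below the mean; overlapping extended
#' events are merged (keeping the larger peak).
#'
#' @param x signal (envelope or rate), regularly sampled.
#' @param t sample times, seconds.
#' @param mu,sg baseline mean and SD of `x`.
#' @param threshold_sd,min_dur_ms detection rule.
#' @return data.frame: `t_start`, `t_end`, `t_peak`, `duration_ms`,
#'   `core_start`, `core_end`, `core_dur_ms`, `peak_value`,
#'   `amplitude_sd` (peak in SD units above the mean).
#' @keywords internal
detect_threshold_events <- function(x, t, mu, sg, threshold_sd, min_dur_ms) {
  empty <- data.frame(t_start = numeric(), t_end = numeric(),
                      t_peak = numeric(), duration_ms = numeric(),
                      core_start = numeric(), core_end = numeric(),
                      core_dur_ms = numeric(), peak_value = numeric(),
                      amplitude_sd = numeric())
  if (sg <= 0) return(empty)
  thr <- mu + threshold_sd * sg
  runs <- true_runs(x > thr)
  if (!nrow(runs)) return(empty)
  dt <- t[2] - t[1]
  dur <- (runs$end - runs$start + 1L) * dt * 1000
  runs <- runs[dur > min_dur_ms, , drop = FALSE]
  if (!nrow(runs)) return(empty)
  below <- x <= mu
  n <- length(x)
  ev <- lapply(seq_len(nrow(runs)), function(k) {
    s <- runs$start[k]; e <- runs$end[k]
    # extend to mean crossings
    lo <- s
    while (lo > 1L && !below[lo - 1L]) lo <- lo - 1L
    hi <- e
    while (hi < n && !below[hi + 1L]) hi <- hi + 1L
    ipk <- s - 1L + which.max(x[s:e])
    data.frame(t_start = t[lo], t_end = t[hi], t_peak = t[ipk],
               duration_ms = (hi - lo) * dt * 1000,
               core_start = t[s], core_end = t[e],
               core_dur_ms = (e - s + 1L) * dt * 1000,
               peak_value = x[ipk],
               amplitude_sd = (x[ipk] - mu) / sg)
  })
  ev <- do.call(rbind, ev)
  # merge overlapping extended events
  keep <- order(ev$t_start)
  ev <- ev[keep, , drop = FALSE]
  merged <- list(ev[1L, ])
  for (k in seq_len(nrow(ev))[-1L]) {
    last <- merged[[length(merged)]]
    if (ev$t_start[k] <= last$t_end) {
      last$t_end <- max(last$t_end, ev$t_end[k])
      last$core_end <- max(last$core_end, ev$core_end[k])
      last$core_dur_ms <- last$core_dur_ms + ev$core_dur_ms[k]
      if (ev$peak_value[k] > last$peak_value) {
        last$peak_value <- ev$peak_value[k]
        last$amplitude_sd <- ev$amplitude_sd[k]
        last$t_peak <- ev$t_peak[k]
      }
      last$duration_ms <- (last$t_end - last$t_start) * 1000
      merged[[length(merged)]] <- last
    } else merged[[length(merged) + 1L]] <- ev[k, ]
  }
  out <- do.call(rbind, merged)
  rownames(out) <- NULL
  out
}

#' Detect candidate ripple events from an envelope
#'
#' @param envobj a [ripple_envelope()].
#' @param params a [ripple_params()] list.
#' @return event data.frame (see [detect_threshold_events()]); zero rows
#'   when nothing crosses threshold.
#' @export
detect_ripples <- function(envobj, params = ripple_params()) {
  detect_threshold_events(envobj$env, envobj$t, envobj$mean, envobj$sd,
                          params$threshold_sd, params$min_dur_ms)
}

#' Smoothed multi-unit instantaneous firing rate
#'
#' Spikes of all units are summed, binned at `mua_bin_ms`, converted to a
#' rate in Hz and Gaussian-smoothed.
#'
#' @param spikes list of [spike_train()] objects (or numeric vectors).
#' @param t_range length-2 numeric, epoch \[start, end\] in seconds.
#' @param params a [ripple_params()] list.
#' @return list with `rate` (Hz), `t` (bin centers, s), `mean`, `sd`.
#' @export
mua_rate <- function(spikes, t_range, params = ripple_params()) {
  allt <- sort(unlist(lapply(spikes, function(s)
    if (inherits(s, "spike_train")) s$t else as.numeric(s))))
  allt <- allt[allt >= t_range[1] & allt <= t_range[2]]
  bw <- params$mua_bin_ms / 1000
  breaks <- seq(t_range[1], t_range[2] + bw, by = bw)
  cnt <- graphics::hist(allt, breaks = breaks, plot = FALSE,
                        include.lowest = TRUE)$counts
  rate <- gauss_smooth(cnt / bw, params$mua_smooth_sd_ms / params$mua_bin_ms)
  list(rate = rate, t = breaks[-1] - bw / 2, mean = mean(rate),
       sd = stats::sd(rate))
}

#' Detect multi-unit activity bursts
#'
#' Applies the same mean + 3 SD / >30 ms threshold rule used for the
#' ripple envelope to the smoothed MUA rate.
#'
#' @inheritParams mua_rate
#' @return event data.frame as in [detect_threshold_events()].
#' @export
mua_bursts <- function(spikes, t_range, params = ripple_params()) {
  mr <- mua_rate(spikes, t_range, params)
  detect_threshold_events(mr$rate, mr$t, mr$mean, mr$sd,
                          params$threshold_sd, params$min_dur_ms)
}

#' Exclude candidate ripples without a coincident MUA burst
#'
#' @param events candidate events from [detect_ripples()].
#' @param spikes list of spike trains (all units).
#' @param t_range rest epoch \[start, end\], seconds.
#' @param params a [ripple_params()] list.
#' @return the subset of `events` overlapping at least one MUA burst.
#' @export
mua_gate <- function(events, spikes, t_range, params = ripple_params()) {
  if (!nrow(events)) return(events)
  mb <- mua_bursts(spikes, t_range, params)
  if (!nrow(mb)) return(events[0L, , drop = FALSE])
  keep <- vapply(seq_len(nrow(events)), function(k)
    any(events$t_start[k] <= mb$t_end & events$t_end[k] >= mb$t_start),
    logical(1))
  events[keep, , drop = FALSE]
}

#' Intrinsic oscillation frequency of one ripple event
#'
#' The band-pass-filtered waveform of the event is multiplied by a
#' Hanning window of the same length and its multitaper spectrum (3
#' Slepian tapers, time-bandwidth product 2) is evaluated; the peak
#' frequency within the ripple band is returned. Events shorter than
#' 50 ms are zero-padded for spectral resolution.
#'
#' @param event one row of a [detect_ripples()] table.
#' @param envobj the [ripple_envelope()] the event came from.
#' @param n_tapers,nw multitaper settings.
#' @param band frequency search band, Hz.
#' @return peak frequency in Hz (`NA` for a degenerate segment).
#' @export
ripple_frequency <- function(event, envobj, n_tapers = 3, nw = 2,
                             band = c(80, 250)) {
  fs <- envobj$fs_hz
  i0 <- findInterval(event$t_start, envobj$t)
  i1 <- findInterval(event$t_end, envobj$t)
  if (i1 - i0 < 8L) return(NA_real_)
  seg <- envobj$filtered[i0:i1]
  n <- length(seg)
  han <- 0.5 - 0.5 * cos(2 * pi * (0:(n - 1L)) / (n - 1L))
  seg <- seg * han
  tp <- dpss_tapers(n, nw = nw, k = n_tapers)
  nfft <- max(2048L, stats::nextn(n, 2))
  spec <- numeric(nfft %/% 2L + 1L)
  for (j in seq_len(n_tapers)) {
    X <- stats::fft(c(seg * tp[, j], numeric(nfft - n)))
    spec <- spec + Mod(X[seq_len(length(spec))])^2
  }
  freq <- (seq_along(spec) - 1L) * fs / nfft
  sel <- freq >= band[1] & freq <= band[2]
  freq[sel][which.max(spec[sel])]
}

#' Full sharp-wave-ripple detection on a rest epoch
#'
#' Runs [ripple_envelope()], [detect_ripples()], optional [mua_gate()]
#' and [ripple_frequency()] and returns the event table.
#'
#' @param lfp [lfp_signal()] restricted to the rest epoch.
#' @param spikes list of spike trains (for the MUA gate); may be `NULL`
#'   when `params$mua_gate` is FALSE.
#' @param params a [ripple_params()] list.
#' @return event data.frame with an added `peak_freq_hz` column;
#'   attribute `n_candidates` records the pre-gate count.
#' @export
detect_swr <- function(lfp, spikes = NULL, params = ripple_params()) {
  envobj <- ripple_envelope(lfp, params)
  ev <- detect_ripples(envobj, params)
  n_cand <- nrow(ev)
  if (params$mua_gate) {
    if (is.null(spikes)) stop("MUA gating requested but no spike trains given")
    ev <- mua_gate(ev, spikes, range(envobj$t), params)
  }
  ev$peak_freq_hz <- if (nrow(ev))
    vapply(seq_len(nrow(ev)), function(k)
      ripple_frequency(ev[k, ], envobj), numeric(1))
  else numeric(0)
  attr(ev, "n_candidates") <- n_cand
  ev
}

#' Session-level ripple metrics
#'
#' @param events gated event table.
#' @param epoch_duration_s rest-epoch duration, seconds.
#' @return one-row data.frame: `n_events`, `rate_per_min`,
#'   `mean_iri_s` (inter-ripple interval between consecutive peaks),
#'   `mean_amplitude_sd`, `mean_duration_ms` (mean-to-mean extended
#'   span), `mean_core_dur_ms` (above-threshold core span, the more
#'   sensitive duration measure since the extended edges ride background
#'   noise), `mean_peak_freq_hz`.
#' @export
ripple_metrics <- function(events, epoch_duration_s) {
  stopifnot(epoch_duration_s > 0)
  ne <- nrow(events)
  data.frame(
    n_events = ne,
    rate_per_min = ne / (epoch_duration_s / 60),
    mean_iri_s = if (ne >= 2L) mean(diff(sort(events$t_peak))) else NA_real_,
    mean_amplitude_sd = if (ne) mean(events$amplitude_sd) else NA_real_,
    mean_duration_ms = if (ne) mean(events$duration_ms) else NA_real_,
    mean_core_dur_ms = if (ne) mean(events$core_dur_ms) else NA_real_,
    mean_peak_freq_hz = if (ne) mean(events$peak_freq_hz, na.rm = TRUE)
                        else NA_real_)
}

#' Per-unit firing statistics within ripple events
#'
#' @param events gated event table.
#' @param spikes list of [spike_train()] objects.
#' @param hist_bin binning of the population participation histogram, as
#'   a fraction (default 0.05, i.e. 5% bins).
#' @return list with `per_unit` (data.frame: `unit_id`,
#'   `spikes_per_ripple`, `participation`) and `participation_hist`
#'   (data.frame: `lo`, `hi`, `prop_cells`).
#' @export
ripple_unit_stats <- function(events, spikes, hist_bin = 0.05) {
  ne <- nrow(events)
  per <- lapply(spikes, function(s) {
    st <- if (inherits(s, "spike_train")) s$t else as.numeric(s)
    id <- if (inherits(s, "spike_train")) as.character(s$unit_id) else NA_character_
    if (!ne) return(data.frame(unit_id = id, spikes_per_ripple = NA_real_,
                               participation = NA_real_))
    cnt <- vapply(seq_len(ne), function(k)
      sum(st >= events$t_start[k] & st <= events$t_end[k]), numeric(1))
    data.frame(unit_id = id, spikes_per_ripple = mean(cnt),
               participation = mean(cnt > 0))
  })
  per <- do.call(rbind, per)
  breaks <- seq(0, 1, by = hist_bin)
  h <- if (ne) graphics::hist(pmin(per$participation, 1 - 1e-9),
                              breaks = breaks, plot = FALSE)$counts
       else integer(length(breaks) - 1L)
  list(per_unit = per,
       participation_hist = data.frame(lo = breaks[-length(breaks)],
                                       hi = breaks[-1],
                                       prop_cells = if (sum(h)) h / sum(h)
                                                    else h))
}

#' Ripple detection across a sweep of thresholds
#'
#' Repeats the full detection and unit statistics at each threshold
#' (default the permissive 2 SD, standard 3 SD and restrictive 6 SD), to
#' show robustness of group differences to the threshold choice.
#'
#' @param lfp rest-epoch [lfp_signal()].
#' @param spikes list of spike trains.
#' @param thresholds numeric vector of SD thresholds.
#' @param params base [ripple_params()].
#' @return named list (one element per threshold) of lists with
#'   `events`, `metrics`, `unit_stats`.
#' @export
threshold_sweep <- function(lfp, spikes, thresholds = c(2, 3, 6),
                            params = ripple_params()) {
  dur <- length(lfp$samples) / lfp$fs_hz
  out <- lapply(thresholds, function(th) {
    p <- params
    p$threshold_sd <- th
    ev <- detect_swr(lfp, spikes, p)
    list(events = ev, metrics = ripple_metrics(ev, dur),
         unit_stats = ripple_unit_stats(ev, spikes))
  })
  names(out) <- paste0("sd", thresholds)
  out
}

#' Event detection from multi-unit activity alone
#'
#' Control variant: population firing bursts detected with the MUA
#' threshold rule define the events directly, with no reference to the
#' LFP. Downstream unit statistics are computable identically.
#'
#' @param spikes list of spike trains.
#' @param t_range epoch \[start, end\], seconds.
#' @param params a [ripple_params()] list.
#' @return event data.frame as in [detect_threshold_events()].
#' @export
detect_events_mua_only <- function(spikes, t_range, params = ripple_params()) {
  mua_bursts(spikes, t_range, params)
}
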