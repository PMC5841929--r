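# Session-level analysis driver and two-group comparison.

#' Run the full single-session analysis
#'
#' Executes the pipeline stages in order — position cleaning/smoothing
#' and velocity, lap detection, unit QC and pyramidal classification,
#' rate maps and spatial metrics, burst statistics (run and rest epochs
#' separately), theta phase locking, Welch PSD, and MUA-gated ripple
#' detection on the rest epoch — and returns all result tables. Counts
#' of items passing each filter are reported via `message()` when
#' `verbose = TRUE`. When the session has no rest epoch the ripple stage
#' is skipped with a logged reason.
#'
#' @param session a session list (`synth_session` or [read_session()]
#'   output) with `position`, `spikes`, `lfp`, `epochs`.
#' @param params optional named list of overrides: `vmin_map` (2 cm/s),
#'   `vmin_theta` (6 cm/s), `bin_cm` (1), `smooth_sd_bins` (1),
#'   `track_length_cm`, `ripple` (a [ripple_params()] list).
#' @param verbose log stage progress and filter counts.
#' @return list of class `session_analysis`: `qc`, `cell_metrics`,
#'   `burst_run`, `burst_rest`, `phase_stats`, `psd`, `ripple_events`,
#'   `ripple_metrics`, `ripple_unit_stats`, `curves` (per included
#'   pyramidal unit), `laps`, `included_units`.
#' @export
analyze_session <- function(session, params = list(), verbose = FALSE) {
  p <- utils::modifyList(list(vmin_map = 2, vmin_theta = 6, bin_cm = 1,
                              smooth_sd_bins = 1, track_length_cm = NULL,
                              ripple = ripple_params()), params)
  if (is.null(p$track_length_cm) && !is.null(session$config))
    p$track_length_cm <- session$config$track_length_cm
  say <- function(...) if (verbose) message(sprintf(...))
  pos <- smooth_positions(clean_positions(session$position))
  vel <- compute_velocity(pos)
  run <- session$epochs[session$epochs$epoch == "run", ][1, ]
  rest <- session$epochs[session$epochs$epoch == "rest", ]
  run_sel <- pos$t >= run$t_start & pos$t < run$t_end
  pos_run <- position_trace(pos$t[run_sel], pos$x[run_sel], pos$y[run_sel])
  vel_run <- vel[run_sel, ]
  laps <- detect_laps(pos_run, track_length_cm = p$track_length_cm)
  say("laps detected: %d", nrow(laps))

  csi <- vapply(session$spikes, function(s)
    if (length(s$t) >= 2L && !is.null(s$amp))
      complex_spike_index(s$t, s$amp)$csi else NA_real_, numeric(1))
  names(csi) <- vapply(session$spikes, function(s) as.character(s$unit_id),
                       character(1))
  qc <- unit_qc_table(session$spikes, csi = csi)
  keep <- qc$status == "included" & qc$cell_class %in% "pyramidal"
  say("units: %d total, %d included pyramidal", nrow(qc), sum(keep))
  spikes_in <- session$spikes[keep]

  run_dur <- run$t_end - run$t_start
  cell_metrics <- NULL; burst_run <- NULL; burst_rest <- NULL
  curves <- list()
  tp <- NULL
  phase_stats <- NULL
  for (s in spikes_in) {
    cm <- spatial_metrics(s, pos_run, vel_run, laps, bin_cm = p$bin_cm,
                          smooth_sd_bins = p$smooth_sd_bins,
                          vmin = p$vmin_map,
                          track_length_cm = p$track_length_cm)
    cell_metrics <- rbind(cell_metrics, cm)
    curves[[as.character(s$unit_id)]] <-
      compute_rate_curves(s, pos_run, laps, bin_cm = p$bin_cm,
                          smooth_sd_bins = p$smooth_sd_bins,
                          track_length_cm = p$track_length_cm)
    tr_run <- s$t[s$t >= run$t_start & s$t < run$t_end]
    br <- burst_statistics(detect_bursts(tr_run), tr_run, run_dur)
    im <- if (length(tr_run) >= 2L)
      isi_histogram_mode(tr_run)$isi_mode_ms else NA_real_
    br$isi_mode_ms <- im
    br$unit_id <- as.character(s$unit_id)
    burst_run <- rbind(burst_run, br)
    if (nrow(rest)) {
      tr_rest <- s$t[s$t >= rest$t_start[1] & s$t < rest$t_end[1]]
      bb <- burst_statistics(detect_bursts(tr_rest), tr_rest,
                             rest$t_end[1] - rest$t_start[1])
      bb$isi_mode_ms <- if (length(tr_rest) >= 2L)
        isi_histogram_mode(tr_rest)$isi_mode_ms else NA_real_
      bb$unit_id <- as.character(s$unit_id)
      burst_rest <- rbind(burst_rest, bb)
    }
  }
  say("place cells: %d of %d pyramidal units",
      sum(cell_metrics$is_place_cell %in% TRUE), length(spikes_in))

  # LFP: theta phase locking on the run epoch, PSD, ripples at rest
  lfp_t <- lfp_times(session$lfp)
  lsel <- lfp_t >= run$t_start & lfp_t < run$t_end
  lfp_run <- lfp_signal(session$lfp$samples[lsel], session$lfp$fs_hz,
                        session$lfp$channel_id, t0 = run$t_start)
  psd <- welch_psd(lfp_run, vel)
  tp <- theta_phase(lfp_run)
  phase_stats <- lapply(spikes_in, function(s) {
    st <- s$t[s$t >= run$t_start & s$t < run$t_end]
    res <- tryCatch(spike_phase_stats(st, tp, vel, vmin = p$vmin_theta),
                    error = function(e) NULL)
    if (is.null(res)) return(NULL)
    data.frame(unit_id = as.character(s$unit_id),
               preferred_phase_deg = res$preferred_phase_deg,
               resultant_r = res$resultant_r, rayleigh_p = res$rayleigh_p,
               kl_div = res$kl_div, mod_index = res$mod_index,
               significant = res$significant, n_spikes = res$n_spikes,
               low_n = res$low_n)
  })
  phase_stats <- do.call(rbind, phase_stats)
  if (!is.null(phase_stats))
    say("theta-modulated units (Rayleigh p < 0.05): %d of %d",
        sum(phase_stats$significant), nrow(phase_stats))

  ripple_events <- NULL; rip_metrics <- NULL; rip_units <- NULL
  if (!nrow(rest)) {
    say("no rest epoch: ripple stage skipped")
  } else {
    rsel <- lfp_t >= rest$t_start[1] & lfp_t < rest$t_end[1]
    lfp_rest <- lfp_signal(session$lfp$samples[rsel], session$lfp$fs_hz,
                           session$lfp$channel_id, t0 = rest$t_start[1])
    ripple_events <- detect_swr(lfp_rest, spikes_in, p$ripple)
    say("ripples: %d candidates, %d after MUA gating",
        attr(ripple_events, "n_candidates"), nrow(ripple_events))
    rip_metrics <- ripple_metrics(ripple_events,
                                  rest$t_end[1] - rest$t_start[1])
    rip_units <- ripple_unit_stats(ripple_events, spikes_in)
  }
  structure(list(qc = qc, cell_metrics = cell_metrics,
                 burst_run = burst_run, burst_rest = burst_rest,
                 phase_stats = phase_stats, psd = psd,
                 ripple_events = ripple_events,
                 ripple_metrics = rip_metrics,
                 ripple_unit_stats = rip_units,
                 curves = curves, laps = laps,
                 included_units = names(curves)),
            class = "session_analysis")
}

#' Compare two groups of analyzed sessions
#'
#' Pools unit-level metrics within each group (spatial, burst, ripple
#' participation; compared with the Mann-Whitney U test) and
#' session-level ripple metrics (one session = one animal; compared
#' with one-way ANOVA), matching the level at which
#' each quantity is measured. Also reports the proportion of
#' theta-modulated units per group with a chi-square test, and the
#' population-vector analysis per group.
#'
#' @param analyses_a,analyses_b lists of [analyze_session()] results.
#' @param group_names labels for the report.
#' @return list with `report` (the [build_report()] table plus the
#'   chi-square row in `theta_proportions`), `pv` (per group: `pv`,
#'   `corr`, `profile_same`, `profile_opposite`).
#' @export
compare_groups <- function(analyses_a, analyses_b,
                           group_names = c("a", "b")) {
  unit_metrics <- function(as_list) {
    cm <- do.call(rbind, lapply(as_list, `[[`, "cell_metrics"))
    br <- do.call(rbind, lapply(as_list, `[[`, "burst_run"))
    bq <- do.call(rbind, lapply(as_list, `[[`, "burst_rest"))
    ru <- do.call(rbind, lapply(as_list, function(a)
      if (!is.null(a$ripple_unit_stats)) a$ripple_unit_stats$per_unit else NULL))
    list(
      field_size_bins = cm$field_size_bins[cm$is_place_cell %in% TRUE],
      si_bits_per_s = cm$si_bits_per_s,
      sparsity = cm$sparsity,
      di = cm$di,
      peak_rate = cm$peak_rate, mean_rate = cm$mean_rate,
      infield_rate = cm$infield_rate, outfield_rate = cm$outfield_rate,
      bursts_per_min = br$bursts_per_min,
      mean_interburst_s = br$mean_interburst_s,
      mean_burst_duration_ms = br$mean_duration_ms,
      pct_spikes_in_burst = br$pct_spikes_in_burst,
      spikes_per_burst = br$spikes_per_burst,
      isi_mode_ms_rest = if (!is.null(bq)) bq$isi_mode_ms else NULL,
      pct_spikes_in_burst_rest = if (!is.null(bq)) bq$pct_spikes_in_burst
                                 else NULL,
      spikes_per_ripple = if (!is.null(ru)) ru$spikes_per_ripple else NULL,
      ripple_participation = if (!is.null(ru)) ru$participation else NULL)
  }
  animal_metrics <- function(as_list) {
    rm_ <- do.call(rbind, lapply(as_list, `[[`, "ripple_metrics"))
    if (is.null(rm_)) return(list())
    list(ripple_rate_per_min = rm_$rate_per_min,
         ripple_iri_s = rm_$mean_iri_s,
         ripple_amplitude_sd = rm_$mean_amplitude_sd,
         ripple_duration_ms = rm_$mean_duration_ms,
         ripple_core_duration_ms = rm_$mean_core_dur_ms,
         ripple_peak_freq_hz = rm_$mean_peak_freq_hz)
  }
  ua <- unit_metrics(analyses_a); ub <- unit_metrics(analyses_b)
  ua <- ua[!vapply(ua, is.null, logical(1))]
  ub <- ub[!vapply(ub, is.null, logical(1))]
  aa <- animal_metrics(analyses_a); ab <- animal_metrics(analyses_b)
  rep_unit <- build_report(ua, ub, test = "mwu", group_names = group_names)
  rep_animal <- if (length(aa) && length(ab))
    build_report(aa, ab, test = "anova1", group_names = group_names)
  else NULL
  report <- rbind(rep_unit, rep_animal)

  theta_prop <- NULL
  pa <- do.call(rbind, lapply(analyses_a, `[[`, "phase_stats"))
  pb <- do.call(rbind, lapply(analyses_b, `[[`, "phase_stats"))
  if (!is.null(pa) && !is.null(pb)) {
    cs <- tryCatch(
      chi_square_proportions(sum(pa$significant), nrow(pa),
                             sum(pb$significant), nrow(pb)),
      error = function(e) list(statistic = NA_real_, p = NA_real_))
    theta_prop <- data.frame(
      k_a = sum(pa$significant), n_a = nrow(pa),
      prop_a = mean(pa$significant),
      k_b = sum(pb$significant), n_b = nrow(pb),
      prop_b = mean(pb$significant),
      chi_square = cs$statistic, p = cs$p)
  }

  group_pv <- function(as_list) {
    curves <- unlist(lapply(as_list, function(a) {
      pc <- a$cell_metrics$unit_id[a$cell_metrics$is_place_cell %in% TRUE]
      a$curves[as.character(pc)]
    }), recursive = FALSE)
    if (length(curves) < 2L) return(NULL)
    pv <- build_population_vectors(curves)
    cc <- pv_correlation_matrix(pv)
    list(pv = pv, corr = cc,
         profile_same = distance_profile(cc, "same"),
         profile_opposite = distance_profile(cc, "opposite"))
  }
  list(report = report, theta_proportions = theta_prop,
       pv = list(a = group_pv(analyses_a), b = group_pv(analyses_b)))
}
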