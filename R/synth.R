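# Synthetic linear-track session generator with full ground truth:
# directionally tuned Gaussian place fields, theta-modulated bursty
# spiking with amplitude attenuation, pink-noise LFP with theta during
# running and injected ripple events (plus coincident MUA bursts) during
# rest. Every analysis stage can be validated against the truth record.

#' Configuration for a synthetic session
#'
#' Per-unit parameters (`field_center_cm`, `field_width_cm`,
#' `peak_rate_hz`, `directional_gain`, `preferred_phase_deg`) are
#' recycled to `n_units`. All rates and durations must be strictly
#' positive; identical configurations (including `seed`) generate
#' bit-identical sessions.
#'
#' @param seed integer RNG seed.
#' @param track_length_cm linear track length (default 170).
#' @param n_laps number of end-to-end traversals (default 10).
#' @param run_speed_cm_s running speed during traversals (default 15).
#' @param behav_fs_hz position sampling rate (default 30, typical diode
#'   tracking).
#' @param n_units number of simulated pyramidal cells (default 20).
#' @param field_center_cm,field_width_cm,peak_rate_hz Gaussian spatial
#'   tuning per unit: center, SD (cm) and in-field peak rate (Hz).
#' @param directional_gain rate multiplier in the non-preferred running
#'   direction, in \[0, 1\]; 1 means direction-independent firing.
#' @param theta_freq_hz theta frequency, Hz (6-12; default 8).
#' @param phase_kappa von Mises concentration of theta phase locking
#'   (0 = no modulation).
#' @param preferred_phase_deg preferred theta firing phase per unit.
#' @param burst_prob probability that an emitted event expands into a
#'   complex burst.
#' @param burst_size_dist named probability vector over burst sizes
#'   (default sizes 2:4 with probabilities 0.6/0.3/0.1).
#' @param intra_burst_isi_ms nominal intra-burst ISI, ms (jittered
#'   +/- 30%).
#' @param amp_attenuation per-spike amplitude multiplier within a burst,
#'   in (0, 1\].
#' @param rest_duration_s duration of the post-run rest epoch.
#' @param rest_rate_hz baseline firing rate during rest, Hz.
#' @param ripple_rate_per_min injected ripple rate during rest.
#' @param ripple_freq_hz,ripple_duration_ms ripple packet carrier
#'   frequency and duration.
#' @param ripple_amp_sd packet envelope peak, in SDs of the background
#'   ripple-band envelope above its mean.
#' @param ripple_mua_rate_hz per-unit Poisson firing rate during each
#'   injected ripple (the coincident MUA burst).
#' @param lfp_fs_hz LFP sampling rate (default 1627.8, the analysis
#'   rate).
#' @param noise_exponent beta of the 1/f^beta LFP background noise.
#' @param refractory_ms absolute refractory period enforced on every
#'   generated train (default 2.5 ms, just above the 2 ms QC bound, as
#'   in well-isolated units).
#' @param theta_amp_sd amplitude of the run-epoch theta sinusoid, in SDs
#'   of the broadband noise.
#' @return validated list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L, track_length_cm = 170, n_laps = 10L,
                         run_speed_cm_s = 15, behav_fs_hz = 30,
                         n_units = 20L,
                         field_center_cm = NULL, field_width_cm = 10,
                         peak_rate_hz = 8, directional_gain = 0.3,
                         theta_freq_hz = 8, phase_kappa = 1,
                         preferred_phase_deg = 180,
                         burst_prob = 0.3,
                         burst_size_dist = c(`2` = 0.6, `3` = 0.3, `4` = 0.1),
                         intra_burst_isi_ms = 5, amp_attenuation = 0.85,
                         rest_duration_s = 120, rest_rate_hz = 0.5,
                         ripple_rate_per_min = 10, ripple_freq_hz = 150,
                         ripple_duration_ms = 80, ripple_amp_sd = 6,
                         ripple_mua_rate_hz = 40,
                         lfp_fs_hz = 1627.8, noise_exponent = 1,
                         theta_amp_sd = 2, refractory_ms = 2.5) {
  if (is.null(field_center_cm))
    field_center_cm <- seq(0.1 * track_length_cm, 0.9 * track_length_cm,
                           length.out = n_units)
  cfg <- list(seed = as.integer(seed), track_length_cm = track_length_cm,
              n_laps = as.integer(n_laps), run_speed_cm_s = run_speed_cm_s,
              behav_fs_hz = behav_fs_hz, n_units = as.integer(n_units),
              field_center_cm = rep_len(field_center_cm, n_units),
              field_width_cm = rep_len(field_width_cm, n_units),
              peak_rate_hz = rep_len(peak_rate_hz, n_units),
              directional_gain = rep_len(directional_gain, n_units),
              theta_freq_hz = theta_freq_hz, phase_kappa = phase_kappa,
              preferred_phase_deg = rep_len(preferred_phase_deg, n_units),
              burst_prob = burst_prob, burst_size_dist = burst_size_dist,
              intra_burst_isi_ms = intra_burst_isi_ms,
              amp_attenuation = amp_attenuation,
              rest_duration_s = rest_duration_s, rest_rate_hz = rest_rate_hz,
              ripple_rate_per_min = ripple_rate_per_min,
              ripple_freq_hz = ripple_freq_hz,
              ripple_duration_ms = ripple_duration_ms,
              ripple_amp_sd = ripple_amp_sd,
              ripple_mua_rate_hz = ripple_mua_rate_hz,
              lfp_fs_hz = lfp_fs_hz, noise_exponent = noise_exponent,
              theta_amp_sd = theta_amp_sd, refractory_ms = refractory_ms)
  with(cfg, {
    if (track_length_cm <= 0 || run_speed_cm_s <= 0 || behav_fs_hz <= 0 ||
        n_laps < 1L || n_units < 1L || rest_duration_s <= 0 ||
        lfp_fs_hz <= 0 || intra_burst_isi_ms <= 0 ||
        ripple_duration_ms <= 0 || ripple_freq_hz <= 0)
      stop("invalid synth_config: rates, durations and counts must be positive")
    if (burst_prob < 0 || burst_prob > 1 ||
        amp_attenuation <= 0 || amp_attenuation > 1 ||
        any(directional_gain < 0 | directional_gain > 1))
      stop("invalid synth_config: probabilities/gains out of range")
    if (phase_kappa < 0 || any(peak_rate_hz <= 0) || any(field_width_cm <= 0))
      stop("invalid synth_config: tuning parameters out of range")
  })
  structure(cfg, class = "synth_config")
}

#' Generate a back-and-forth linear-track trajectory
#'
#' Traversals between the track ends (exactly `cfg$n_laps` of them,
#' alternating direction, starting rightward from 0), sampled at
#' `cfg$behav_fs_hz`. Running speed fluctuates smoothly around
#' `run_speed_cm_s` (two slow sinusoidal components with random phases,
#' about +/- 25% peak); besides being realistic, the fluctuation
#' decorrelates theta phase from track position across laps, which a
#' constant speed would artificially lock together. Small Gaussian
#' positional jitter (0.15 cm) emulates tracking noise; `y` jitters
#' around the track midline.
#'
#' @param cfg a [synth_config()].
#' @return a [position_trace()] covering the run epoch, with attribute
#'   `run_duration_s`.
#' @export
generate_trajectory <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  dt <- 1 / cfg$behav_fs_hz
  L <- cfg$track_length_cm
  ph1 <- stats::runif(1, 0, 2 * pi)
  ph2 <- stats::runif(1, 0, 2 * pi)
  speed_at <- function(tt)
    cfg$run_speed_cm_s * pmax(0.3, 1 + 0.18 * sin(2 * pi * 0.11 * tt + ph1) +
                                     0.10 * sin(2 * pi * 0.37 * tt + ph2))
  # integrate until n_laps end-to-end traversals are complete
  n_max <- ceiling(2.2 * cfg$n_laps * L / cfg$run_speed_cm_s / dt)
  x <- numeric(n_max)
  x[1] <- 0
  dir <- 1
  laps_done <- 0L
  i <- 1L
  while (laps_done < cfg$n_laps && i < n_max) {
    i <- i + 1L
    xn <- x[i - 1L] + dir * speed_at((i - 2L) * dt) * dt
    if (xn >= L) { xn <- L - (xn - L); dir <- -1; laps_done <- laps_done + 1L }
    else if (xn <= 0) { xn <- -xn; dir <- 1; laps_done <- laps_done + 1L }
    x[i] <- xn
  }
  x <- x[seq_len(i)]
  t <- (seq_len(i) - 1L) * dt
  x <- pmin(L, pmax(0, x + stats::rnorm(i, 0, 0.15)))
  y <- 5 + stats::rnorm(i, 0, 0.15)
  p <- position_trace(t, x, y)
  attr(p, "run_duration_s") <- t[i]
  p
}

# draw burst sizes from the configured distribution
draw_burst_sizes <- function(n, dist) {
  sizes <- as.integer(names(dist))
  sample(sizes, n, replace = TRUE, prob = dist)
}

# Enforce an absolute refractory period on a sorted spike train: a greedy
# pass keeps a spike only if it follows the last kept spike by at least
# refractory_ms. When a kept burst member collides, the whole burst is
# removed (so truth bursts never end up with internal gaps), and the pass
# repeats until stable.
enforce_refractory <- function(t, burst_id = integer(length(t)),
                               refractory_ms = 2.5) {
  keep <- rep(TRUE, length(t))
  repeat {
    idx <- which(keep)
    if (length(idx) < 2L) break
    tk <- t[idx]
    drop_local <- logical(length(idx))
    last <- tk[1L]
    for (k in seq_along(tk)[-1L]) {
      if ((tk[k] - last) * 1000 < refractory_ms) drop_local[k] <- TRUE
      else last <- tk[k]
    }
    if (!any(drop_local)) break
    dropped <- idx[drop_local]
    bad_bursts <- setdiff(unique(burst_id[dropped]), 0L)
    keep[dropped] <- FALSE
    if (length(bad_bursts)) keep[burst_id %in% bad_bursts] <- FALSE
  }
  keep
}

#' Generate ground-truth-annotated spike trains
#'
#' Spiking is an inhomogeneous Poisson process simulated by Bernoulli
#' thinning on a 1 ms grid: rate = Gaussian spatial tuning x directional
#' gain x von Mises theta modulation (normalized to unit mean over
#' phase). Each emitted event expands into a complex burst with
#' probability `burst_prob`; intra-burst ISIs jitter around
#' `intra_burst_isi_ms` and successive spike amplitudes shrink by
#' `amp_attenuation`. The event rate is divided by the expected burst
#' multiplication factor, so the configured tuning (`peak_rate_hz`,
#' `rest_rate_hz`) is the expected total spike rate including burst
#' spikes. During the rest epoch units fire at `rest_rate_hz` with the
#' same burst statistics. Per-spike 8-D feature
#' vectors are drawn from a unit-specific Gaussian cluster (two features
#' per tetrode channel analog), supporting isolation-distance testing.
#'
#' Odd-numbered units prefer rightward running, even-numbered leftward;
#' the non-preferred direction is scaled by `directional_gain`.
#'
#' @param cfg a [synth_config()].
#' @param pos trajectory from [generate_trajectory()].
#' @param rest_range optional rest epoch \[start, end\] in seconds
#'   (default immediately after the run epoch, `rest_duration_s` long).
#' @return list with `spikes` (list of [spike_train()]) and `truth`
#'   (list: `tuning` per-unit data.frame; `spike_truth` per-spike
#'   data.frame with columns `unit`, `t`, `burst_id`, `theta_phase_deg`,
#'   `in_run`).
#' @export
generate_spikes <- function(cfg, pos, rest_range = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  if (nrow(pos) < 2L) stop("empty trajectory")
  set.seed(cfg$seed + 1L)
  T_run <- pos$t[nrow(pos)]
  if (is.null(rest_range))
    rest_range <- c(T_run, T_run + cfg$rest_duration_s)
  dt <- 1e-3
  tg <- seq(pos$t[1] + dt / 2, T_run, by = dt)
  xg <- stats::approx(pos$t, pos$x, xout = tg)$y
  dirg <- sign(c(diff(xg), 0))
  dirg[dirg == 0] <- 1
  phg <- (360 * cfg$theta_freq_hz * tg) %% 360
  vm <- if (cfg$phase_kappa > 0)
    function(ph, mu) exp(cfg$phase_kappa * cos((ph - mu) * pi / 180)) /
      besselI(cfg$phase_kappa, 0)
  else function(ph, mu) rep(1, length(ph))
  tr <- seq(rest_range[1] + dt / 2, rest_range[2], by = dt)
  # burst expansion multiplies the emitted event count; divide the event
  # rate by the expected burst factor so the configured tuning is the
  # total spike rate (burst spikes included)
  sizes_d <- as.integer(names(cfg$burst_size_dist))
  burst_factor <- 1 + cfg$burst_prob *
    (sum(sizes_d * cfg$burst_size_dist) / sum(cfg$burst_size_dist) - 1)
  spikes <- vector("list", cfg$n_units)
  truth_rows <- vector("list", cfg$n_units)
  tuning <- data.frame(unit = seq_len(cfg$n_units),
                       field_center_cm = cfg$field_center_cm,
                       field_width_cm = cfg$field_width_cm,
                       peak_rate_hz = cfg$peak_rate_hz,
                       directional_gain = cfg$directional_gain,
                       preferred_dir = ifelse(seq_len(cfg$n_units) %% 2L == 1L,
                                              "right", "left"),
                       preferred_phase_deg = cfg$preferred_phase_deg,
                       phase_kappa = cfg$phase_kappa)
  burst_counter <- 0L
  for (u in seq_len(cfg$n_units)) {
    pref <- if (tuning$preferred_dir[u] == "right") 1 else -1
    lam <- cfg$peak_rate_hz[u] *
      exp(-(xg - cfg$field_center_cm[u])^2 / (2 * cfg$field_width_cm[u]^2)) *
      ifelse(dirg == pref, 1, cfg$directional_gain[u]) *
      vm(phg, cfg$preferred_phase_deg[u])
    ev_run <- tg[stats::runif(length(tg)) < pmin(0.95, lam / burst_factor * dt)]
    ev_rest <- tr[stats::runif(length(tr)) < cfg$rest_rate_hz / burst_factor * dt]
    ev <- c(ev_run, ev_rest)
    if (!length(ev)) {
      spikes[[u]] <- spike_train(u, numeric(0),
                                 amp = matrix(numeric(0), 0, 4),
                                 features = matrix(numeric(0), 0, 8),
                                 width_us = 300)
      truth_rows[[u]] <- NULL
      next
    }
    is_burst <- stats::runif(length(ev)) < cfg$burst_prob
    t_all <- ev
    order_within <- rep(1L, length(ev))
    bid <- integer(length(ev))
    if (any(is_burst)) {
      sizes <- draw_burst_sizes(sum(is_burst), cfg$burst_size_dist)
      ids <- burst_counter + seq_len(sum(is_burst))
      burst_counter <- burst_counter + sum(is_burst)
      bid[is_burst] <- ids
      extra_t <- list(); extra_o <- list(); extra_b <- list()
      bi <- which(is_burst)
      for (k in seq_along(bi)) {
        isis <- cfg$intra_burst_isi_ms / 1000 *
          stats::runif(sizes[k] - 1L, 0.7, 1.3)
        extra_t[[k]] <- ev[bi[k]] + cumsum(isis)
        extra_o[[k]] <- 1L + seq_len(sizes[k] - 1L)
        extra_b[[k]] <- rep(ids[k], sizes[k] - 1L)
      }
      t_all <- c(t_all, unlist(extra_t))
      order_within <- c(order_within, unlist(extra_o))
      bid <- c(bid, unlist(extra_b))
    }
    o <- sort.list(t_all)
    t_all <- t_all[o]; order_within <- order_within[o]; bid <- bid[o]
    keep <- enforce_refractory(t_all, bid, cfg$refractory_ms)
    t_all <- t_all[keep]; order_within <- order_within[keep]; bid <- bid[keep]
    # amplitudes: fixed per-unit 4-channel profile, 5% noise, burst decay
    profile <- 150 + 100 * stats::runif(4)
    att <- cfg$amp_attenuation^(order_within - 1L)
    amp <- outer(att, profile) * (1 + 0.05 * stats::rnorm(length(t_all)))
    mu_f <- stats::rnorm(8, 0, 25)
    feats <- matrix(stats::rnorm(8L * length(t_all), 0, 4), ncol = 8,
                    byrow = TRUE) + matrix(mu_f, length(t_all), 8,
                                           byrow = TRUE)
    spikes[[u]] <- spike_train(u, t_all, amp = amp, features = feats,
                               width_us = 300)
    in_run <- t_all <= T_run
    truth_rows[[u]] <- data.frame(
      unit = u, t = t_all, burst_id = bid,
      theta_phase_deg = ifelse(in_run,
                               (360 * cfg$theta_freq_hz * t_all) %% 360,
                               NA_real_),
      in_run = in_run)
  }
  list(spikes = spikes,
       truth = list(tuning = tuning,
                    spike_truth = do.call(rbind, truth_rows)))
}

#' Generate the session LFP with injected ripple events
#'
#' The background is 1/f^beta ("pink") noise, spectrally shaped in the
#' frequency domain and normalized to unit SD. During run epochs a theta
#' sinusoid is added. During rest epochs, sinusoidal ripple packets
#' with a tapered-cosine (Tukey) envelope, flat over the central half
#' (carrier `ripple_freq_hz`, duration `ripple_duration_ms`), are
#' injected at `ripple_rate_per_min` at
#' non-overlapping times (bounded redraws, error on failure); the packet
#' peak is scaled to `ripple_amp_sd` SDs of the background (smoothed)
#' ripple-band envelope above its mean, matching the units of the
#' detection threshold. For every injected ripple a coincident Poisson
#' MUA burst (`ripple_mua_rate_hz` per unit) is returned for appending
#' to the spike trains.
#'
#' @param cfg a [synth_config()].
#' @param epochs data.frame with columns `epoch` ("run"/"rest"),
#'   `t_start`, `t_end`, partitioning the session.
#' @param max_retries redraw bound for non-overlapping placement.
#' @return list with `lfp` (an [lfp_signal()] spanning the session),
#'   `ripples` (data.frame: `t_start`, `t_end`, `t_center`, `freq_hz`),
#'   `mua_spikes` (list over units of extra spike times).
#' @export
generate_lfp <- function(cfg, epochs, max_retries = 1000L) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed + 2L)
  fs <- cfg$lfp_fs_hz
  t_end <- max(epochs$t_end)
  n <- floor(t_end * fs)
  tt <- (seq_len(n) - 1L) / fs
  # spectrally shaped Gaussian noise, unit SD
  wh <- stats::rnorm(n)
  X <- stats::fft(wh)
  f <- c(0, seq_len(n - 1L)) * fs / n
  f[f > fs / 2] <- fs - f[f > fs / 2]
  shape <- c(0, 1 / f[-1]^(cfg$noise_exponent / 2))
  x <- Re(stats::fft(X * shape, inverse = TRUE)) / n
  x <- x / stats::sd(x)
  run_rows <- epochs[epochs$epoch == "run", , drop = FALSE]
  for (k in seq_len(nrow(run_rows))) {
    sel <- tt >= run_rows$t_start[k] & tt < run_rows$t_end[k]
    x[sel] <- x[sel] + cfg$theta_amp_sd *
      cos(2 * pi * cfg$theta_freq_hz * tt[sel])
  }
  rest_rows <- epochs[epochs$epoch == "rest", , drop = FALSE]
  ripples <- list()
  mua <- replicate(cfg$n_units, numeric(0), simplify = FALSE)
  dur_s <- cfg$ripple_duration_ms / 1000
  for (k in seq_len(nrow(rest_rows))) {
    r0 <- rest_rows$t_start[k]; r1 <- rest_rows$t_end[k]
    sel <- tt >= r0 & tt < r1
    if (cfg$ripple_rate_per_min <= 0 || sum(sel) < 20L * fs / 100) next
    # background ripple-band envelope statistics of this rest segment
    bg <- ripple_envelope(lfp_signal(x[sel], fs, t0 = r0))
    A <- bg$mean + cfg$ripple_amp_sd * bg$sd
    n_rip <- round(cfg$ripple_rate_per_min * (r1 - r0) / 60)
    centers <- numeric(0)
    tries <- 0L
    while (length(centers) < n_rip) {
      cand <- stats::runif(1, r0 + dur_s, r1 - dur_s)
      if (!length(centers) || all(abs(cand - centers) > dur_s + 0.25)) {
        centers <- c(centers, cand)
      } else {
        tries <- tries + 1L
        if (tries > max_retries)
          stop("could not place non-overlapping ripples; lower the rate")
      }
    }
    centers <- sort(centers)
    for (ct in centers) {
      i0 <- max(1L, round((ct - dur_s / 2) * fs) + 1L)
      i1 <- min(n, i0 + round(dur_s * fs) - 1L)
      m <- i1 - i0 + 1L
      # tapered-cosine (Tukey) envelope, flat over the central half, so the
      # nominal duration is also the duration at amplitude
      u <- (0:(m - 1L)) / (m - 1L)
      tuk <- rep(1, m)
      lo <- u < 0.25
      hi <- u > 0.75
      tuk[lo] <- 0.5 * (1 - cos(pi * u[lo] / 0.25))
      tuk[hi] <- 0.5 * (1 - cos(pi * (1 - u[hi]) / 0.25))
      x[i0:i1] <- x[i0:i1] +
        A * tuk * cos(2 * pi * cfg$ripple_freq_hz * (tt[i0:i1] - ct))
      for (u in seq_len(cfg$n_units)) {
        nsp <- stats::rpois(1, cfg$ripple_mua_rate_hz * dur_s)
        if (nsp > 0)
          mua[[u]] <- c(mua[[u]],
                        stats::runif(nsp, tt[i0], tt[i1]))
      }
      ripples[[length(ripples) + 1L]] <- data.frame(
        t_start = tt[i0], t_end = tt[i1], t_center = ct,
        freq_hz = cfg$ripple_freq_hz)
    }
  }
  ripdf <- if (length(ripples)) do.call(rbind, ripples)
           else data.frame(t_start = numeric(), t_end = numeric(),
                           t_center = numeric(), freq_hz = numeric())
  list(lfp = lfp_signal(x, fs, "synth"), ripples = ripdf, mua_spikes = mua)
}

#' Simulate a complete annotated session
#'
#' Assembles trajectory, spikes and LFP into one session: a run epoch
#' (the `n_laps` traversals, starting at t = 0) followed by a rest epoch
#' of `rest_duration_s` during which the animal sits at the track end.
#' Ripple-coincident MUA spikes are merged into the unit spike trains
#' (with burst membership 0 and unattenuated amplitudes).
#'
#' @param cfg a [synth_config()].
#' @return object of class `synth_session`: list with `position`
#'   (whole-session [position_trace()]), `spikes` (list of
#'   [spike_train()]), `lfp` ([lfp_signal()]), `epochs` (data.frame),
#'   `truth` (list: `tuning`, `spike_truth`, `ripples`), `config`.
#' @export
simulate_session <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  pos_run <- generate_trajectory(cfg)
  T_run <- pos_run$t[nrow(pos_run)]
  epochs <- data.frame(epoch = c("run", "rest"),
                       t_start = c(0, T_run),
                       t_end = c(T_run, T_run + cfg$rest_duration_s))
  sp <- generate_spikes(cfg, pos_run,
                        rest_range = c(T_run, T_run + cfg$rest_duration_s))
  lf <- generate_lfp(cfg, epochs)
  # extend position through rest (stationary at the final track position)
  set.seed(cfg$seed + 3L)
  t_rest <- seq(T_run + 1 / cfg$behav_fs_hz, T_run + cfg$rest_duration_s,
                by = 1 / cfg$behav_fs_hz)
  x_end <- pos_run$x[nrow(pos_run)]
  pos <- position_trace(
    c(pos_run$t, t_rest),
    c(pos_run$x, pmin(cfg$track_length_cm,
                      pmax(0, x_end + stats::rnorm(length(t_rest), 0, 0.15)))),
    c(pos_run$y, 5 + stats::rnorm(length(t_rest), 0, 0.15)))
  spikes <- sp$spikes
  for (u in seq_along(spikes)) {
    extra <- sort(lf$mua_spikes[[u]])
    if (!length(extra)) next
    s <- spikes[[u]]
    # respect the unit's refractory period when merging ripple spikes
    ref_s <- cfg$refractory_ms / 1000
    ok <- logical(length(extra))
    last_kept <- -Inf
    for (k in seq_along(extra)) {
      near_orig <- length(s$t) &&
        min(abs(s$t - extra[k])) < ref_s
      if (!near_orig && extra[k] - last_kept >= ref_s) {
        ok[k] <- TRUE
        last_kept <- extra[k]
      }
    }
    extra <- extra[ok]
    if (!length(extra)) next
    profile <- if (nrow(s$amp)) apply(s$amp, 2, stats::median)
               else 150 + 100 * stats::runif(4)
    amp_x <- outer(rep(1, length(extra)), profile) *
      (1 + 0.05 * stats::rnorm(length(extra)))
    mu_f <- if (nrow(s$features)) colMeans(s$features) else stats::rnorm(8, 0, 25)
    ft_x <- matrix(stats::rnorm(8L * length(extra), 0, 4), ncol = 8) +
      matrix(mu_f, length(extra), 8, byrow = TRUE)
    t_new <- c(s$t, extra)
    o <- sort.list(t_new)
    spikes[[u]] <- spike_train(s$unit_id, t_new[o],
                               amp = rbind(s$amp, amp_x)[o, , drop = FALSE],
                               features = rbind(s$features, ft_x)[o, , drop = FALSE],
                               width_us = s$width_us)
  }
  structure(list(position = pos, spikes = spikes, lfp = lf$lfp,
                 epochs = epochs,
                 truth = c(sp$truth, list(ripples = lf$ripples)),
                 config = cfg),
            class = "synth_session")
}

#' @export
print.synth_session <- function(x, ...) {
  cat(sprintf(paste0("<synth_session> %d units, %.0f s run + %.0f s rest, ",
                     "%d injected ripples (seed %d)\n"),
              length(x$spikes),
              x$epochs$t_end[1], diff(unlist(x$epochs[2, 2:3])),
              nrow(x$truth$ripples), x$config$seed))
  invisible(x)
}
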