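# Complex-spike index, burst detection, burst statistics, ISI mode.

test_that("CSI hits its endpoints on constructed monotone bursts", {
  # clean attenuating 3-spike bursts with 5 ms ISIs -> all pairs positive
  starts <- seq(0, 10, by = 0.5)
  t <- as.vector(vapply(starts, function(s) s + c(0, 0.005, 0.010),
                        numeric(3)))
  amp <- rep(c(300, 250, 200), length(starts))
  res <- complex_spike_index(t, amp)
  expect_equal(res$csi, 100)
  expect_equal(res$neg, 0L)

  # increasing amplitudes within bursts -> all pairs negative
  res2 <- complex_spike_index(t, rep(c(200, 250, 300), length(starts)))
  expect_equal(res2$csi, -100)

  # ISI below the 3 ms refractory bound counts negative even if attenuating
  res3 <- complex_spike_index(c(0, 0.002), c(300, 200))
  expect_equal(res3$csi, -100)

  # pairs beyond 15 ms are ignored entirely
  res4 <- complex_spike_index(c(0, 0.5, 1.0), c(300, 200, 100))
  expect_equal(res4$n_pairs, 0L)
  expect_equal(res4$csi, 0)

  expect_warning(nn <- complex_spike_index(1, 5), "undefined")
  expect_true(is.na(nn$csi))
})

test_that("CSI is near zero for amplitude-shuffled trains and scale invariant", {
  set.seed(31)
  n <- 4001
  t <- cumsum(rep(0.005, n))
  amp <- runif(n, 100, 300)
  res <- complex_spike_index(t, amp)
  expect_gt(res$n_pairs, 2000)
  expect_lt(abs(res$csi), 10)
  # uniform amplitude scaling changes nothing
  expect_equal(complex_spike_index(t, amp * 7.3)$csi, res$csi)
  # bounded
  expect_lte(abs(res$csi), 100)
})

test_that("burst chaining matches the rule and a brute-force oracle", {
  # 0, 5, 8 ms -> one burst of 3 spikes spanning 8 ms
  b <- detect_bursts(ms(c(0, 5, 8)))
  expect_equal(nrow(b), 1L)
  expect_equal(b$n_spikes, 3L)
  expect_equal(b$duration_ms, 8, tolerance = 1e-9)

  # 0, 12 ms -> no burst
  expect_equal(nrow(detect_bursts(ms(c(0, 12)))), 0L)

  # transitive chaining: 0, 6, 12 ms is one 3-spike burst
  expect_equal(detect_bursts(ms(c(0, 6, 12)))$n_spikes, 3L)

  # oracle equivalence on a random train: explicit loop over spikes
  set.seed(32)
  t <- sort(runif(800, 0, 20))
  oracle <- local({
    groups <- list(); cur <- 1L
    for (i in 2:length(t)) {
      if ((t[i] - t[i - 1]) * 1000 <= 10) cur <- c(cur, i)
      else { if (length(cur) >= 2L) groups[[length(groups) + 1L]] <- cur
             cur <- i }
    }
    if (length(cur) >= 2L) groups[[length(groups) + 1L]] <- cur
    groups
  })
  got <- detect_bursts(t)
  expect_equal(nrow(got), length(oracle))
  expect_equal(got$t_start, vapply(oracle, function(g) t[g[1]], numeric(1)),
               tolerance = 1e-12)
  expect_equal(got$n_spikes, lengths(oracle))

  # partition property: every spike in at most one burst, bursts disjoint
  mem <- attr(got, "spike_burst")
  expect_equal(length(mem), length(t))
  for (b_id in unique(mem[mem > 0]))
    expect_true(all(diff(which(mem == b_id)) == 1L))
  expect_true(all(diff(got$t_start) > 0))
  expect_true(all(got$t_end[-nrow(got)] < got$t_start[-1]))
})

test_that("burst statistics summarize counts, intervals and percentages", {
  # 12 bursts in 2 minutes -> 6 per minute
  starts <- seq(0, by = 10, length.out = 12)
  t <- as.vector(vapply(starts, function(s) s + c(0, 0.005), numeric(2)))
  st <- burst_statistics(detect_bursts(t), t, epoch_duration_s = 120)
  expect_equal(st$bursts_per_min, 6)
  expect_equal(st$pct_spikes_in_burst, 100)
  expect_equal(st$spikes_per_burst, 2)
  expect_equal(st$mean_interburst_s, 10, tolerance = 1e-9)
  expect_equal(st$mean_duration_ms, 5, tolerance = 1e-9)

  # no bursts: interval/duration undefined
  st0 <- burst_statistics(detect_bursts(c(1, 2, 3)), c(1, 2, 3), 60)
  expect_equal(st0$bursts_per_min, 0)
  expect_true(is.na(st0$mean_duration_ms))
})

test_that("percentage of spikes in bursts rises with generator burst_prob", {
  pcts <- vapply(c(0, 0.2, 0.5), function(bp) {
    cfg <- synth_config(seed = 5, n_units = 2, n_laps = 4, burst_prob = bp,
                        rest_duration_s = 30)
    pos <- generate_trajectory(cfg)
    sp <- generate_spikes(cfg, pos)
    t <- sp$spikes[[1]]$t
    burst_statistics(detect_bursts(t), t, max(t))$pct_spikes_in_burst
  }, numeric(1))
  expect_true(all(diff(pcts) > 0))
  # burst_prob = 0 -> essentially no bursts (chance coincidences only)
  expect_lt(pcts[1], 5)
})

test_that("ISI histogram mode finds the dominant interval population", {
  # regular 100 ms train
  m <- isi_histogram_mode(cumsum(rep(0.1, 200)))
  expect_gt(m$isi_mode_ms, 90)
  expect_lt(m$isi_mode_ms, 110)

  # bursty train dominated by 5 ms ISIs: mode in the 2-15 ms burst range
  starts <- seq(0, by = 0.4, length.out = 150)
  t <- as.vector(vapply(starts, function(s) s + c(0, 0.005, 0.010),
                        numeric(3)))
  mb <- isi_histogram_mode(t)
  expect_gt(mb$isi_mode_ms, 2)
  expect_lt(mb$isi_mode_ms, 15)

  # bimodal mixture: majority component wins
  set.seed(33)
  isis <- c(rexp(300, 1 / 0.005) + 0.003, rexp(100, 1 / 0.2) + 0.05)
  mm <- isi_histogram_mode(cumsum(sample(isis)))
  expect_lt(mm$isi_mode_ms, 20)
})
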