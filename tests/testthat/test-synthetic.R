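test_that("simulated trains hit their target rate and reproduce by seed", {
  lay <- make_multiwell(1, 4)
  cfg <- sim_config(layout = lay, duration_s = 100, baseline_rate_hz = 2,
                    burst_rate_hz = 0, seed = 7)
  tr <- simulate_trains(cfg)
  counts <- firing_rates(tr)$n_spikes
  for (n in counts) expect_lt(abs(n - 200), 3 * sqrt(200))

  tr2 <- simulate_trains(cfg)
  expect_equal(tibble::as_tibble(tr), tibble::as_tibble(tr2))
  tr3 <- simulate_trains(sim_config(layout = lay, duration_s = 100,
                                    baseline_rate_hz = 2, burst_rate_hz = 0,
                                    seed = 8))
  expect_false(isTRUE(all.equal(nrow(tr), nrow(tr3))) &&
               isTRUE(all.equal(tr$time_s, tr3$time_s)))

  silent <- simulate_trains(sim_config(layout = lay, duration_s = 10,
                                       baseline_rate_hz = 0,
                                       burst_rate_hz = 0))
  expect_equal(nrow(silent), 0L)

  # refractory thinning holds
  isi <- tibble::as_tibble(tr) |>
    dplyr::group_by(channel) |>
    dplyr::summarise(min_isi = min(diff(time_s)), .groups = "drop")
  expect_true(all(isi$min_isi >= cfg$refractory_s))
})

test_that("well-synchronised bursts are shared within, not across, wells", {
  lay <- make_multiwell(4, 8, well_spacing_um = 3000)
  cfg <- sim_config(layout = lay, duration_s = 60, baseline_rate_hz = 0.5,
                    burst_rate_hz = 0.1, burst_size = 8, well_sync = TRUE,
                    seed = 3)
  tr <- simulate_trains(cfg)
  bt <- attr(tr, "burst_times")
  expect_length(bt, 4L)
  # burst realisations differ across wells
  expect_false(isTRUE(all.equal(bt[["0"]], bt[["1"]])))
})

test_that("rendering inserts templates at spike samples with attenuation", {
  lay <- make_multiwell(1, 2)
  cfg <- sim_config(layout = lay, duration_s = 1, rate_hz = 10000,
                    noise_sigma_uv = 0, template_peak_uv = -50)
  trains <- new_spike_trains(tibble::tibble(channel = 0L, time_s = 0.5),
                             duration = 1, channel_ids = lay$channel)
  rec <- render_recording(trains, cfg)
  home <- rec$signal[1, ]
  expect_equal(min(home), -50, tolerance = 1e-9)
  expect_equal(which.min(home), round(0.5 * cfg$rate_hz) + 1L)
  # neighbour at one pitch sees the exponential attenuation (or nothing if
  # below the 2% insertion floor)
  d <- sqrt((lay$x_um[2] - lay$x_um[1])^2 + (lay$y_um[2] - lay$y_um[1])^2)
  expected <- -50 * exp(-d / cfg$attenuation_um)
  neigh <- min(rec$signal[2, ])
  if (exp(-d / cfg$attenuation_um) >= 0.02) {
    expect_equal(neigh, expected, tolerance = 1e-9)
  } else {
    expect_equal(neigh, 0)
  }
})

test_that("low-noise end-to-end detection has perfect recall and precision", {
  # the noise floor must be positive for the median-based threshold to be
  # defined; at 50x peak-to-noise the chain should be error-free
  lay <- make_multiwell(1, 4)
  # attenuation shortened so neighbour spikes stay below the low threshold,
  # and a moderate 20x peak-to-noise so filter ringing stays below it too
  cfg <- sim_config(layout = lay, duration_s = 10, rate_hz = 30000,
                    baseline_rate_hz = 2, burst_rate_hz = 0.2,
                    template_peak_uv = -20, noise_sigma_uv = 1,
                    attenuation_um = 30, seed = 13)
  tr <- simulate_trains(cfg)
  rec <- render_recording(tr, cfg)
  filt <- apply_filter(rec)
  det <- detect_spikes(filt)
  truth <- spikes_true <- tibble::as_tibble(tr)
  got <- tibble::as_tibble(det$spikes)
  expect_equal(nrow(got), nrow(truth))
  # every true spike matched within 1 ms on its channel
  for (ch in unique(truth$channel)) {
    tt <- truth$time_s[truth$channel == ch]
    gg <- got$time_s[got$channel == ch]
    expect_equal(length(gg), length(tt))
    expect_true(all(abs(sort(gg) - sort(tt)) <= 0.001))
  }
})

test_that("doubling the noise doubles the estimated noise level", {
  lay <- make_multiwell(1, 2)
  tr <- new_spike_trains(tibble::tibble(channel = integer(), time_s = double()),
                         duration = 5, channel_ids = lay$channel)
  cfg1 <- sim_config(layout = lay, duration_s = 5, rate_hz = 10000,
                     noise_sigma_uv = 4, seed = 2)
  cfg2 <- sim_config(layout = lay, duration_s = 5, rate_hz = 10000,
                     noise_sigma_uv = 8, seed = 2)
  s1 <- estimate_noise(render_recording(tr, cfg1)$signal[1, ])
  s2 <- estimate_noise(render_recording(tr, cfg2)$signal[1, ])
  expect_equal(s2 / s1, 2, tolerance = 0.02)
})

test_that("measured SNR grows monotonically with template amplitude", {
  lay <- make_multiwell(1, 2)
  snrs <- sapply(c(-30, -60, -90), function(peak) {
    cfg <- sim_config(layout = lay, duration_s = 10, rate_hz = 20000,
                      baseline_rate_hz = 3, burst_rate_hz = 0,
                      template_peak_uv = peak, noise_sigma_uv = 5, seed = 4)
    tr <- simulate_trains(cfg)
    filt <- apply_filter(render_recording(tr, cfg))
    det <- detect_spikes(filt)
    mean(snr(filt, det$cutouts)$snr, na.rm = TRUE)
  })
  expect_true(all(diff(snrs) > 0))
})

test_that("fluorescence rendering yields one calcium event per burst", {
  lay <- make_multiwell(1, 4)
  cfg <- sim_config(layout = lay, duration_s = 60, baseline_rate_hz = 0,
                    burst_size = 30, intra_burst_isi_s = 0.005,
                    ca_gain = 0.05, seed = 6)
  ev <- list()
  for (b in c(5, 16, 27, 38, 49)) {
    for (ch in lay$channel) {
      ev[[length(ev) + 1]] <- tibble::tibble(
        channel = ch, time_s = b + (0:29) * 0.005 + ch * 1e-4)
    }
  }
  trains <- new_spike_trains(dplyr::bind_rows(ev), duration = 60,
                             channel_ids = lay$channel)
  fl <- render_fluorescence(trains, cfg)
  d <- compute_dff(fl)
  found <- detect_calcium_events(d, threshold = 0.3, min_separation_s = 3)
  expect_equal(nrow(found), 5L)

  # empty trains give a flat trace at F0
  none <- new_spike_trains(tibble::tibble(channel = integer(),
                                          time_s = double()),
                           duration = 10, channel_ids = lay$channel)
  flat <- render_fluorescence(none, cfg)
  expect_equal(flat$f, rep(cfg$ca_f0, length(flat$f)))

  # seed reproducibility with noise
  cfgn <- sim_config(layout = lay, duration_s = 10, ca_noise_sd = 1, seed = 9)
  trn <- simulate_trains(cfgn)
  expect_equal(render_fluorescence(trn, cfgn)$f,
               render_fluorescence(trn, cfgn)$f)
})

test_that("full-chain firing-rate recovery within 10% at 10x peak-to-noise", {
  lay <- make_multiwell(1, 8)
  rel_err <- sapply(1:20, function(seed) {
    cfg <- sim_config(layout = lay, duration_s = 10, rate_hz = 30000,
                      baseline_rate_hz = 2, burst_rate_hz = 0.2,
                      template_peak_uv = -50, noise_sigma_uv = 5, seed = seed)
    tr <- simulate_trains(cfg)
    det <- detect_spikes(apply_filter(render_recording(tr, cfg)))
    truth <- firing_rates(tr)$rate_hz
    got <- firing_rates(det$spikes)$rate_hz
    max(abs(got - truth) / pmax(truth, 1e-9))
  })
  expect_true(all(rel_err <= 0.10))
})

test_that("within-well correlation exceeds across-well correlation", {
  hits <- sapply(1:20, function(seed) {
    lay <- make_multiwell(4, 8, well_spacing_um = 3000)
    cfg <- sim_config(layout = lay, duration_s = 120, baseline_rate_hz = 1,
                      burst_rate_hz = 0.2, burst_size = 10,
                      well_sync = TRUE, seed = seed)
    tr <- simulate_trains(cfg)
    cm <- unclass(correlation_matrix(bin_spiketrains(tr, 0.010)))
    same <- outer(lay$well_id, lay$well_id, `==`)
    diag(same) <- NA
    within <- mean(cm[same & !is.na(same)], na.rm = TRUE)
    across <- mean(cm[!same], na.rm = TRUE)
    within > across
  })
  expect_gte(mean(hits), 0.95)
})
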