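make_spikes <- function(times, channel = 0L, duration = max(times, 1),
                        ids = unique(channel)) {
  new_spike_trains(tibble::tibble(channel = rep_len(channel, length(times)),
                                  time_s = times),
                   duration = duration, channel_ids = ids)
}

test_that("firing rates are count over duration, silent channels included", {
  sp <- make_spikes(seq(0.5, 119.5, by = 1), duration = 120, ids = 0:1)
  fr <- firing_rates(sp)
  expect_equal(fr$rate_hz[fr$channel == 0], 1.0)
  expect_equal(fr$rate_hz[fr$channel == 1], 0)

  set.seed(21)
  ts <- sort(runif(rpois(1, 2 * 100), 0, 100))
  sp2 <- make_spikes(ts, duration = 100, ids = 0L)
  se <- sqrt(2 / 100)
  expect_lt(abs(firing_rates(sp2)$rate_hz - 2), 3 * se)

  bad <- make_spikes(numeric(0), duration = 1, ids = 0L)
  attr(bad, "duration") <- 0
  expect_error(firing_rates(bad), "duration")
})

test_that("active-channel rule uses a strict threshold", {
  rates <- tibble::tibble(channel = 0:3, rate_hz = c(0.6, 0.5, 0, 2))
  act <- active_channels(rates)
  expect_equal(act$active, c(TRUE, FALSE, FALSE, TRUE))
  none <- active_channels(tibble::tibble(channel = 0:1, rate_hz = c(0, 0)))
  expect_false(any(none$active))
})

test_that("snr is mean peak over trace SD, scale-invariant, NA when silent", {
  rate <- 1000
  n <- 10000
  trace <- rep(0, n)
  trace[c(1000, 2000)] <- c(1, -1)       # give the trace a tiny known sd
  rec <- new_recording(matrix(trace, 1), rate)
  sd0 <- sd(trace)
  snips <- matrix(c(0, -40, 0, 0, -50, 0, 0, -60, 0), nrow = 3, byrow = TRUE)
  co <- new_cutouts(snips, tibble::tibble(channel = 0L, time_s = c(1, 2, 3),
                                          sample = c(1000, 2000, 3000)),
                    pre_samples = 1, post_samples = 1, rate = rate)
  out <- snr(rec, co)
  expect_equal(out$snr, 50 / sd0)

  rec2 <- rec; rec2$signal <- rec2$signal * 7
  co2 <- co; co2$snippets <- co2$snippets * 7
  expect_equal(snr(rec2, co2)$snr, out$snr)

  # channel without events reports NA
  rec3 <- new_recording(matrix(rnorm(2 * n), 2), rate)
  out3 <- snr(rec3, co)
  expect_true(is.na(out3$snr[out3$channel == 1]))
})

test_that("binning uses half-open bins and conserves counts", {
  sp <- make_spikes(c(0.005, 0.015), duration = 0.02, ids = 0L)
  m <- bin_spiketrains(sp, 0.010)
  expect_equal(as.vector(m), c(1L, 1L))

  edge <- make_spikes(c(0.010), duration = 0.03, ids = 0L)
  m2 <- bin_spiketrains(edge, 0.010)
  expect_equal(as.vector(m2), c(0L, 1L, 0L))

  set.seed(31)
  ts <- sort(runif(500, 0, 60))
  sp3 <- new_spike_trains(
    tibble::tibble(channel = sample(0:3, 500, replace = TRUE), time_s = ts),
    duration = 60, channel_ids = 0:3)
  m3 <- bin_spiketrains(sp3, 0.010)
  fr <- firing_rates(sp3)
  expect_equal(unname(rowSums(m3)), as.numeric(fr$n_spikes))
})

test_that("correlation matrix matches the two-pass covariance oracle", {
  set.seed(41)
  for (i in 1:20) {
    m <- matrix(rpois(6 * 200, 2), nrow = 6)
    got <- correlation_matrix(m)
    expect_equal(unclass(got), oracle_corr(m), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
  # identical trains correlate at 1; symmetry, unit diagonal
  two <- rbind(c(1, 0, 2, 0, 3), c(1, 0, 2, 0, 3))
  cm <- correlation_matrix(two)
  expect_equal(cm[1, 2], 1)
  expect_equal(unclass(cm), t(unclass(cm)))
  expect_equal(diag(unclass(cm)), rep(1, 2), ignore_attr = TRUE)
  # zero-variance channel reported missing
  cm2 <- correlation_matrix(rbind(c(1, 2, 3), c(0, 0, 0)))
  expect_true(is.na(cm2[1, 2]))
  expect_error(correlation_matrix(matrix(1, 2, 1)), "2 bins")
})

test_that("independent Poisson trains are essentially uncorrelated", {
  set.seed(51)
  off_diag <- replicate(40, {
    sp <- new_spike_trains(
      tibble::tibble(channel = rep(0:1, each = 1000),
                     time_s = c(sort(runif(1000, 0, 200)),
                                sort(runif(1000, 0, 200)))),
      duration = 200, channel_ids = 0:1)
    correlation_matrix(bin_spiketrains(sp, 0.010))[1, 2]
  })
  expect_gte(mean(abs(off_diag) < 0.05), 0.95)
})

test_that("burst detection matches the run-scan oracle exactly", {
  set.seed(61)
  for (i in 1:1000) {
    n <- sample(0:60, 1)
    times <- sort(runif(n, 0, 10))
    max_isi <- runif(1, 0.01, 0.5)
    min_spikes <- sample(2:5, 1)
    got <- detect_bursts(times, max_isi, min_spikes)
    want <- oracle_bursts(times, max_isi, min_spikes)
    expect_equal(as.data.frame(got), want, ignore_attr = TRUE)
  }
})

test_that("burst examples: tonic trains, embedded bursts, separated bursts", {
  expect_equal(nrow(detect_bursts(seq(0, 10), 0.1, 3)), 0L)

  burst <- 5 + (0:9) * 0.01             # 10 spikes at 100 Hz
  bg <- c(1, 2.5, 8, 9.7)
  b <- detect_bursts(sort(c(bg, burst)), 0.02, 5)
  expect_equal(nrow(b), 1L)
  expect_equal(b$n_spikes, 10L)

  two <- c(1 + (0:5) * 0.01, 3 + (0:5) * 0.01)
  expect_equal(nrow(detect_bursts(two, 0.02, 5)), 2L)

  all_b <- detect_bursts_all(make_spikes(burst, duration = 10, ids = 0L),
                             0.02, 5)
  expect_equal(all_b$channel, 0L)
})

test_that("box summary follows the interpolation-quantile and whisker rules", {
  b <- box_summary(1:8)
  expect_equal(b$median, oracle_quantile(1:8, 0.5))
  expect_equal(b$q1, 2.75)
  expect_equal(b$q3, 6.25)
  expect_equal(b$median, 4.5)

  set.seed(71)
  for (i in 1:20) {
    x <- rnorm(sample(5:100, 1))
    b <- box_summary(x)
    expect_equal(b$q1, oracle_quantile(x, 0.25))
    expect_equal(b$q3, oracle_quantile(x, 0.75))
    expect_gte(b$whisker_low, min(x))
    expect_lte(b$whisker_high, max(x))
    expect_true(all(b$outliers < b$whisker_low | b$outliers > b$whisker_high))
  }

  const <- box_summary(rep(3, 10))
  expect_equal(const$iqr, 0)
  expect_length(const$outliers, 0)

  ext <- box_summary(c(1:10, 100))
  expect_true(100 %in% ext$outliers)
  expect_error(box_summary(numeric(0)), "finite")
})

test_that("firing map joins rates onto electrode coordinates", {
  lay <- make_multiwell(4, 8, well_spacing_um = 3000)
  rates <- tibble::tibble(channel = lay$channel,
                          rate_hz = as.numeric(lay$well_id))
  fm <- firing_map(rates, lay)
  expect_equal(nrow(fm), nrow(lay))
  expect_equal(fm$x_um, lay$x_um)
  # well-grouped means recover the per-well values
  means <- fm |> dplyr::group_by(well_id) |>
    dplyr::summarise(m = mean(rate_hz), .groups = "drop")
  expect_equal(means$m, as.numeric(sort(unique(lay$well_id))))

  expect_error(firing_map(tibble::tibble(channel = 999, rate_hz = 1), lay),
               "not present")
})
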