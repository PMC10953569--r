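test_that("noise estimate recovers the Gaussian SD and scales linearly", {
  set.seed(10)
  x <- rnorm(1e6)
  expect_equal(estimate_noise(x), 1, tolerance = 0.01)
  expect_equal(estimate_noise(3 * x), 3, tolerance = 0.01)
  expect_equal(estimate_noise(rep(0, 100)), 0)
  expect_error(estimate_noise(numeric(0)), "empty")
  expect_error(estimate_noise(c(1, NA)), "finite")

  # scale equivariance on arbitrary traces
  for (i in 1:20) {
    y <- rnorm(500, sd = runif(1, 0.1, 10))
    c0 <- runif(1, -5, 5)
    expect_equal(estimate_noise(c0 * y), abs(c0) * estimate_noise(y),
                 tolerance = 1e-12)
  }
})

test_that("detector finds injected events at the right samples", {
  set.seed(5)
  rate <- 30000
  x <- rnorm(rate)                      # 1 s of sigma = 1 noise
  at <- c(5000L, 15000L, 25000L)
  for (a in at) x <- inject_event(x, a, peak = -10)
  det <- detect_spikes(make_test_recording(x, rate))
  expect_equal(nrow(det$spikes), 3L)
  samples <- round(det$spikes$time_s * rate) + 1L
  expect_true(all(abs(samples - at) <= 1))
})

test_that("all-zero and flat recordings are handled without events", {
  rec <- make_test_recording(rep(0, 1000))
  expect_warning(det <- detect_spikes(rec), "flat")
  expect_equal(nrow(det$spikes), 0L)
  expect_equal(det$skipped_channels, 0L)
})

test_that("dead time keeps only the first of two close events", {
  set.seed(6)
  rate <- 30000
  x <- rnorm(rate)
  cfg <- detection_config(dead_time_s = 0.002)
  # two events half a dead time apart
  x <- inject_event(x, 10000L, -12)
  x <- inject_event(x, 10000L + 30L, -12)   # 1 ms later
  det <- detect_spikes(make_test_recording(x, rate), cfg)
  expect_equal(nrow(det$spikes), 1L)
  expect_equal(round(det$spikes$time_s * rate) + 1L, 10000L, tolerance = 1)
})

test_that("detection equals the brute-force crossing-scan oracle", {
  set.seed(77)
  for (i in 1:100) {
    n <- sample(500:10000, 1)
    x <- rnorm(n)
    n_ev <- sample(0:5, 1)
    if (n_ev > 0) {
      at <- sample(seq(20, n - 20), n_ev)
      for (a in at) x <- inject_event(x, a, peak = runif(1, -15, -6))
    }
    polarity <- sample(c("negative", "positive", "both"), 1)
    dead_s <- sample(c(0, 0.001, 0.003), 1)
    cfg <- detection_config(polarity = polarity, dead_time_s = dead_s)
    rate <- 10000
    sigma <- estimate_noise(x)
    expected <- oracle_detect(x, 5 * sigma, round(dead_s * rate), polarity)
    det <- detect_spikes(new_recording(matrix(x, 1), rate), cfg)
    got <- as.integer(round(det$spikes$time_s * rate) + 1L)
    expect_identical(got, as.integer(expected))
  }
})

test_that("false-event rate on pure noise is low at multiplier 5", {
  set.seed(123)
  rate <- 30000
  x <- rnorm(10 * rate)                  # 10 s
  det <- detect_spikes(make_test_recording(x, rate))
  expect_lt(nrow(det$spikes) / 10, 0.2)  # events per second
})

test_that("cutouts have the configured window and extremum alignment", {
  set.seed(8)
  rate <- 30000
  x <- rnorm(2 * rate)
  x <- inject_event(x, 30000L, -10)
  x <- inject_event(x, 6L, -10)          # too close to the start
  cfg <- detection_config(pre_s = 0.001, post_s = 0.001)
  det <- detect_spikes(make_test_recording(x, rate), cfg)
  co <- det$cutouts
  expect_equal(ncol(co$snippets), 61L)   # 30 + 30 + 1 at 30 kHz
  expect_equal(attr(co, "n_dropped"), 1L)
  # alignment sample is the polarity extremum of each snippet
  for (j in seq_len(nrow(co$snippets))) {
    expect_equal(which.min(co$snippets[j, ]), co$pre_samples + 1L)
  }
})

test_that("sorting separates two distinct waveform templates", {
  set.seed(9)
  rate <- 30000
  n_each <- 100
  w <- 31
  t <- seq(-15, 15)
  tmpl1 <- -8 * exp(-t^2 / 8)                       # narrow, deep
  tmpl2 <- -4 * exp(-t^2 / 40)                      # wide, shallow
  snips <- rbind(
    t(replicate(n_each, tmpl1 + rnorm(w, sd = 0.3))),
    t(replicate(n_each, tmpl2 + rnorm(w, sd = 0.3)))
  )
  truth <- rep(1:2, each = n_each)
  co <- new_cutouts(snips,
                    tibble::tibble(channel = 0L, time_s = seq_len(2 * n_each) / 100,
                                   sample = seq_len(2 * n_each)),
                    pre_samples = 15, post_samples = 15, rate = rate)
  srt <- sort_spikes(co)
  expect_equal(srt$n_units, 2L)
  agree <- max(mean(srt$labels == truth), mean(srt$labels == 3 - truth))
  expect_gte(agree, 0.95)

  td <- tidy(srt)
  expect_equal(nrow(td), 2 * n_each)
  expect_true(all(c("event", "unit", "PC1", "PC2") %in% names(td)))
  g <- glance(srt)
  expect_equal(g$n_units, 2L)
})

test_that("degenerate and permuted cutout sets sort consistently", {
  snips <- matrix(rep(-5, 20 * 11), nrow = 20)
  co <- new_cutouts(snips, tibble::tibble(channel = 0L, time_s = 1:20 / 10,
                                          sample = 1:20),
                    pre_samples = 5, post_samples = 5, rate = 1000)
  expect_warning(srt <- sort_spikes(co), "zero variance")
  expect_equal(srt$n_units, 1L)

  expect_error(sort_spikes(new_cutouts(matrix(rnorm(33), 3),
                                       tibble::tibble(channel = 0L,
                                                      time_s = 1:3,
                                                      sample = 1:3),
                                       5, 5, 1000)),
               "at least")

  # permutation invariance up to label names
  set.seed(11)
  t <- seq(-15, 15)
  snips <- rbind(
    t(replicate(30, -8 * exp(-t^2 / 8) + rnorm(31, sd = 0.2))),
    t(replicate(30, -3 * exp(-t^2 / 60) + rnorm(31, sd = 0.2)))
  )
  ev <- tibble::tibble(channel = 0L, time_s = 1:60 / 10, sample = 1:60)
  co1 <- new_cutouts(snips, ev, 15, 15, 1000)
  perm <- sample(60)
  co2 <- new_cutouts(snips[perm, ], ev[perm, ], 15, 15, 1000)
  s1 <- sort_spikes(co1)
  s2 <- sort_spikes(co2)
  expect_equal(s2$n_units, s1$n_units)
  # same partition of events after undoing the permutation
  relabel <- s2$labels[order(perm)]
  agree <- max(mean(relabel == s1$labels),
               mean((3 - relabel) == s1$labels))
  expect_equal(agree, 1)
})
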