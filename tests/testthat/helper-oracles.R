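# Independent reference implementations used to cross-check the package.
# These are deliberately naive (plain loops, direct formulas) and share no
# code with the implementation under test.

# O(n) loop scan: threshold crossing opens an event, re-crossing closes it,
# timestamp at the window extremum, dead-time by sequential acceptance.
oracle_detect <- function(x, thr, dead_samples, polarity = "negative") {
  y <- switch(polarity, negative = -x, positive = x, both = abs(x))
  peaks <- integer(0)
  i <- 1L
  n <- length(y)
  while (i <= n) {
    if (y[i] > thr) {
      j <- i
      while (j < n && y[j + 1L] > thr) j <- j + 1L
      win <- i:j
      peaks <- c(peaks, win[which.max(y[win])])
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (dead_samples > 0 && length(peaks) > 1) {
    kept <- peaks[1]
    for (p in peaks[-1]) {
      if (p - kept[length(kept)] >= dead_samples) kept <- c(kept, p)
    }
    peaks <- kept
  }
  peaks
}

# Burst run scan: walk the train accumulating runs of ISIs <= max_isi.
oracle_bursts <- function(times, max_isi, min_spikes) {
  out <- list()
  n <- length(times)
  if (n == 0) return(data.frame(start_s = double(), end_s = double(),
                                n_spikes = integer()))
  run_start <- 1L
  for (i in seq_len(n)) {
    closes <- (i == n) || (times[i + 1L] - times[i] > max_isi)
    if (closes) {
      count <- i - run_start + 1L
      if (count >= min_spikes) {
        out[[length(out) + 1L]] <- data.frame(start_s = times[run_start],
                                              end_s = times[i],
                                              n_spikes = count)
      }
      run_start <- i + 1L
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(start_s = double(), end_s = double(), n_spikes = integer())
}

# Two-pass covariance correlation: explicit mean, then explicit cross sums.
oracle_corr <- function(m) {
  k <- nrow(m)
  out <- matrix(NA_real_, k, k)
  mu <- rowMeans(m)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      di <- m[i, ] - mu[i]
      dj <- m[j, ] - mu[j]
      denom <- sqrt(sum(di^2) * sum(dj^2))
      out[i, j] <- if (denom == 0) NA_real_ else sum(di * dj) / denom
    }
  }
  out
}

# Linear-interpolation quantile (type-7 definition written out directly).
oracle_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# Insert a biphasic event (sharp negative deflection) into a trace.
inject_event <- function(x, at, peak, half_width = 3L) {
  idx <- (at - half_width):(at + half_width)
  shape <- peak * exp(-((idx - at)^2) / (half_width / 1.5)^2)
  x[idx] <- x[idx] + shape
  x
}

make_test_recording <- function(x, rate = 30000) {
  new_recording(matrix(x, nrow = 1), rate = rate)
}
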