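# Threshold spike detection and PCA sorting. The detector applies, per
# channel, a threshold of multiplier * median(|x|) / 0.6745 on the band-pass
# filtered trace x: the median absolute value of zero-mean Gaussian noise is
# 0.6745 sigma, so the quotient is a spike-robust estimate of the noise SD.

#' Detection configuration
#'
#' @param multiplier threshold multiplier in noise SDs (default 5).
#' @param noise_divisor quantile constant relating median absolute value to
#'   the Gaussian SD (default 0.6745).
#' @param polarity `"negative"` (default; extracellular spikes are
#'   predominantly negative-going), `"positive"`, or `"both"`.
#' @param dead_time_s minimum gap between events on one channel (s).
#' @param pre_s,post_s cutout window before/after the alignment extremum (s).
#' @return a list of class `detection_config`.
#' @export
detection_config <- function(multiplier = 5, noise_divisor = 0.6745,
                             polarity = c("negative", "positive", "both"),
                             dead_time_s = 0.001, pre_s = 0.001,
                             post_s = 0.002) {
  polarity <- match.arg(polarity)
  if (multiplier <= 0 || noise_divisor <= 0) {
    stop("multiplier and noise_divisor must be > 0", call. = FALSE)
  }
  if (dead_time_s < 0 || pre_s <= 0 || post_s <= 0) {
    stop("dead_time_s must be >= 0 and the cutout window > 0", call. = FALSE)
  }
  structure(list(multiplier = multiplier, noise_divisor = noise_divisor,
                 polarity = polarity, dead_time_s = dead_time_s,
                 pre_s = pre_s, post_s = post_s),
            class = "detection_config")
}

#' Robust noise estimate from the median absolute signal value
#'
#' `sigma_hat = median(|x|) / noise_divisor`; with the default divisor
#' 0.6745 this is unbiased for the SD of Gaussian noise and nearly
#' insensitive to the sparse large deflections contributed by spikes.
#'
#' @param trace numeric vector (uV), finite, non-empty.
#' @param noise_divisor see [detection_config()].
#' @return estimated noise SD (uV).
#' @export
estimate_noise <- function(trace, noise_divisor = 0.6745) {
  if (length(trace) == 0) stop("empty trace", call. = FALSE)
  if (!all(is.finite(trace))) stop("trace contains non-finite values", call. = FALSE)
  stats::median(abs(trace)) / noise_divisor
}

# Event scan on one polarity-rectified trace: an event opens when y crosses
# above thr and closes at the re-crossing; its sample is the within-window
# argmax of y. Events closer than dead_time to the previously kept event are
# discarded (first extremum wins).
scan_events <- function(y, thr, dead_samples) {
  above <- y > thr
  if (!any(above)) return(integer(0))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  peaks <- vapply(runs, function(k) {
    i0 <- starts[k]; i1 <- ends[k]
    i0 + which.max(y[i0:i1]) - 1L
  }, integer(1))
  if (dead_samples > 0 && length(peaks) > 1) {
    keep <- peaks[1]
    last <- peaks[1]
    for (p in peaks[-1]) {
      if (p - last >= dead_samples) {
        keep <- c(keep, p)
        last <- p
      }
    }
    peaks <- keep
  }
  peaks
}

rectify <- function(x, polarity) {
  switch(polarity, negative = -x, positive = x, both = abs(x))
}

#' Detect spikes by noise-scaled threshold crossing
#'
#' Per channel, the threshold is `multiplier * median(|x|) / noise_divisor`.
#' A crossing opens an event window that closes at the re-crossing; the event
#' timestamp is the window extremum in the detection polarity, and events
#' closer than `dead_time_s` to the previous kept event are discarded. The
#' recording should be band-pass filtered first (see [apply_filter()]); the
#' detector does not filter.
#'
#' @param recording a filtered `mea_recording`.
#' @param config a [detection_config()].
#' @return list with `spikes` (an `mea_spikes` tibble), `cutouts` (an
#'   `mea_cutouts` with the configured window; boundary events are kept in
#'   `spikes` but dropped from `cutouts`, count in attribute `n_dropped`),
#'   and `skipped_channels` (flat channels with zero noise estimate).
#' @export
detect_spikes <- function(recording, config = detection_config()) {
  stopifnot(inherits(recording, "mea_recording"),
            inherits(config, "detection_config"))
  rate <- recording$rate
  dead <- round(config$dead_time_s * rate)
  ids <- recording$channel_ids
  skipped <- ids[0]
  events <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    x <- recording$signal[i, ]
    if (length(x) == 0) next
    sigma <- estimate_noise(x, config$noise_divisor)
    if (sigma == 0) {
      skipped <- c(skipped, ids[i])
      next
    }
    thr <- config$multiplier * sigma
    peaks <- scan_events(rectify(x, config$polarity), thr, dead)
    if (length(peaks)) {
      events[[i]] <- tibble::tibble(channel = rep(ids[i], length(peaks)),
                                    time_s = (peaks - 1L) / rate,
                                    sample = peaks)
    }
  }
  ev <- dplyr::bind_rows(events)
  if (nrow(ev) == 0) {
    ev <- tibble::tibble(channel = ids[0], time_s = double(), sample = integer())
  }
  spikes <- new_spike_trains(ev[, c("channel", "time_s")],
                             duration = rec_duration(recording),
                             channel_ids = ids)
  if (length(skipped)) {
    warning(sprintf("channel(s) %s skipped: flat trace (zero noise estimate)",
                    paste(skipped, collapse = ", ")), call. = FALSE)
  }
  cutouts <- extract_cutouts(recording, spikes, config$pre_s, config$post_s)
  list(spikes = spikes, cutouts = cutouts, skipped_channels = skipped)
}

#' Extract waveform cutouts around spike timestamps
#'
#' Each event yields a snippet of `pre_s * rate` samples before and
#' `post_s * rate` after its alignment sample (inclusive). Events too close
#' to the recording boundary are dropped; the dropped count is reported in
#' attribute `n_dropped` of the result.
#'
#' @param recording the (filtered) source `mea_recording`.
#' @param spikes an `mea_spikes` object with timestamps into `recording`.
#' @param pre_s,post_s window extent in seconds.
#' @return an `mea_cutouts` object.
#' @export
extract_cutouts <- function(recording, spikes, pre_s = 0.001, post_s = 0.002) {
  rate <- recording$rate
  pre <- round(pre_s * rate)
  post <- round(post_s * rate)
  n <- ncol(recording$signal)
  ch_row <- match(spikes$channel, recording$channel_ids)
  samp <- round(spikes$time_s * rate) + 1L
  ok <- samp - pre >= 1L & samp + post <= n
  n_dropped <- sum(!ok)
  idx <- which(ok)
  snips <- matrix(0, nrow = length(idx), ncol = pre + post + 1L)
  for (j in seq_along(idx)) {
    k <- idx[j]
    snips[j, ] <- recording$signal[ch_row[k], (samp[k] - pre):(samp[k] + post)]
  }
  out <- new_cutouts(
    snips,
    tibble::tibble(channel = spikes$channel[idx], time_s = spikes$time_s[idx],
                   sample = samp[idx]),
    pre_samples = pre, post_samples = post, rate = rate)
  attr(out, "n_dropped") <- n_dropped
  out
}

mean_silhouette <- function(x, labels) {
  mean(cluster::silhouette(labels, stats::dist(x))[, "sil_width"])
}

#' PCA spike sorting
#'
#' Projects the cutout matrix onto its top principal components and clusters
#' the scores with k-means; the number of units is chosen by the mean
#' silhouette width over `k in 2..k_max`, falling back to a single unit when
#' no split reaches silhouette 0.5 (or when the cutouts have no variance).
#'
#' @param cutouts an `mea_cutouts` with at least `2 * n_components` events.
#' @param n_components number of principal components to keep (default 2).
#' @param k number of units, or `"auto"` (default) for silhouette selection.
#' @param k_max largest k tried under `"auto"`.
#' @param seed RNG seed for k-means initialisation.
#' @return an object of class `mea_sort` with fields `labels` (1..n_units),
#'   `n_units`, `projections` (events x n_components score matrix),
#'   `component_count`, `silhouette` (selection table), `events`.
#' @export
sort_spikes <- function(cutouts, n_components = 2, k = "auto", k_max = 5,
                        seed = 1) {
  stopifnot(inherits(cutouts, "mea_cutouts"))
  m <- cutouts$snippets
  if (nrow(m) < 2 * n_components) {
    stop(sprintf("need at least %d events to project onto %d components",
                 2 * n_components, n_components), call. = FALSE)
  }
  if (all(apply(m, 2, stats::var) < .Machine$double.eps)) {
    warning("cutouts have zero variance; returning a single unit", call. = FALSE)
    return(new_sort(rep(1L, nrow(m)), matrix(0, nrow(m), n_components),
                    n_components, NULL, cutouts$events))
  }
  n_components <- min(n_components, ncol(m), nrow(m) - 1L)
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  proj <- pc$x[, seq_len(n_components), drop = FALSE]
  sil_tab <- NULL
  if (identical(k, "auto")) {
    ks <- seq(2L, min(k_max, nrow(proj) - 1L))
    sil <- withr::with_seed(as.integer(seed), vapply(ks, function(kk) {
      fit <- stats::kmeans(proj, centers = kk, nstart = 10, iter.max = 50)
      mean_silhouette(proj, fit$cluster)
    }, numeric(1)))
    sil_tab <- tibble::tibble(k = ks, mean_silhouette = sil)
    k <- if (max(sil) >= 0.5) ks[which.max(sil)] else 1L
  }
  labels <- if (k == 1L) {
    rep(1L, nrow(proj))
  } else {
    withr::with_seed(as.integer(seed),
                     stats::kmeans(proj, centers = k, nstart = 10,
                                   iter.max = 50)$cluster)
  }
  new_sort(as.integer(labels), proj, n_components, sil_tab, cutouts$events)
}

new_sort <- function(labels, projections, component_count, silhouette, events) {
  structure(list(labels = labels, n_units = length(unique(labels)),
                 projections = projections, component_count = component_count,
                 silhouette = silhouette, events = events),
            class = "mea_sort")
}

#' @export
print.mea_sort <- function(x, ...) {
  cat(sprintf("<mea_sort> %d event(s) in %d unit(s) on %d component(s)\n",
              length(x$labels), x$n_units, x$component_count))
  invisible(x)
}

#' Tidy and glance methods for meapipe results
#'
#' `tidy()` returns one row per event (or per snippet sample for cutouts);
#' `glance()` returns a one-row model summary.
#'
#' @param x an `mea_sort` or `mea_cutouts` object.
#' @param ... unused.
#' @name tidy_mea
#' @export
tidy.mea_sort <- function(x, ...) {
  proj <- tibble::as_tibble(x$projections, .name_repair = "minimal")
  names(proj) <- paste0("PC", seq_len(ncol(proj)))
  dplyr::bind_cols(
    tibble::tibble(event = seq_along(x$labels),
                   channel = x$events$channel,
                   time_s = x$events$time_s,
                   unit = x$labels),
    proj)
}

#' @rdname tidy_mea
#' @export
glance.mea_sort <- function(x, ...) {
  tibble::tibble(
    n_events = length(x$labels),
    n_units = x$n_units,
    n_components = x$component_count,
    mean_silhouette = if (is.null(x$silhouette) || x$n_units == 1) NA_real_
                      else max(x$silhouette$mean_silhouette)
  )
}
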