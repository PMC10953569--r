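# Channel and network statistics on detected spike trains.

#' Per-channel firing rates
#'
#' @param spikes an `mea_spikes` object with positive duration.
#' @return tibble with `channel` (every channel on the roster, silent ones
#'   included) and `rate_hz = count / duration`.
#' @export
firing_rates <- function(spikes) {
  dur <- attr(spikes, "duration")
  if (is.null(dur) || dur <= 0) stop("duration must be > 0", call. = FALSE)
  ids <- attr(spikes, "channel_ids")
  counts <- table(factor(spikes$channel, levels = ids))
  tibble::tibble(channel = ids, n_spikes = as.integer(counts),
                 rate_hz = as.integer(counts) / dur)
}

#' Active-channel rule
#'
#' A channel is active when its spike rate strictly exceeds the threshold
#' (default 0.5 Hz); a channel at exactly the threshold is inactive.
#'
#' @param rates tibble from [firing_rates()] (or any frame with `channel`
#'   and `rate_hz`).
#' @param threshold_hz activity threshold (Hz).
#' @return the input with a logical `active` column added.
#' @export
active_channels <- function(rates, threshold_hz = 0.5) {
  stopifnot(all(c("channel", "rate_hz") %in% names(rates)),
            all(rates$rate_hz >= 0))
  dplyr::mutate(tibble::as_tibble(rates), active = .data$rate_hz > threshold_hz)
}

#' Per-channel signal-to-noise ratio
#'
#' SNR is the mean absolute spike peak amplitude divided by the standard
#' deviation of the channel's entire filtered trace. Channels without any
#' event get `NA` (undefined, not zero).
#'
#' @param filtered_recording the band-pass filtered `mea_recording`.
#' @param cutouts an `mea_cutouts` from the same recording; the peak
#'   amplitude of each event is its alignment-sample value.
#' @return tibble with `channel`, `n_events`, `mean_peak_uv`, `trace_sd_uv`,
#'   `snr`.
#' @export
snr <- function(filtered_recording, cutouts) {
  stopifnot(inherits(filtered_recording, "mea_recording"),
            inherits(cutouts, "mea_cutouts"))
  ids <- filtered_recording$channel_ids
  peaks <- if (nrow(cutouts$snippets)) {
    abs(cutouts$snippets[, cutouts$pre_samples + 1L])
  } else numeric(0)
  per_ev <- tibble::tibble(channel = cutouts$events$channel, peak = peaks)
  sds <- apply(filtered_recording$signal, 1, stats::sd)
  base <- tibble::tibble(channel = ids, trace_sd_uv = sds)
  agg <- per_ev |>
    dplyr::group_by(.data$channel) |>
    dplyr::summarise(n_events = dplyr::n(),
                     mean_peak_uv = mean(.data$peak), .groups = "drop")
  out <- dplyr::left_join(base, agg, by = "channel")
  out$n_events[is.na(out$n_events)] <- 0L
  dplyr::mutate(out, snr = .data$mean_peak_uv / .data$trace_sd_uv)[,
    c("channel", "n_events", "mean_peak_uv", "trace_sd_uv", "snr")]
}

#' Bin spike trains into a channels x bins count matrix
#'
#' Half-open bins `[k*bin_s, (k+1)*bin_s)`: a spike exactly at a bin edge
#' belongs to the later bin. Row sums equal the per-channel spike counts.
#'
#' @param spikes an `mea_spikes` object.
#' @param bin_s bin width in seconds (default 0.010).
#' @return integer matrix, one row per roster channel (rownames = channel
#'   ids), `ceiling(duration / bin_s)` columns.
#' @export
bin_spiketrains <- function(spikes, bin_s = 0.010) {
  stopifnot(bin_s > 0)
  dur <- attr(spikes, "duration")
  ids <- attr(spikes, "channel_ids")
  n_bins <- max(1L, as.integer(ceiling(dur / bin_s - 1e-9)))
  bin <- pmin(floor(spikes$time_s / bin_s), n_bins - 1L)
  m <- matrix(0L, nrow = length(ids), ncol = n_bins,
              dimnames = list(as.character(ids), NULL))
  if (nrow(spikes)) {
    idx <- cbind(match(spikes$channel, ids), bin + 1L)
    for (j in seq_len(nrow(idx))) m[idx[j, 1], idx[j, 2]] <- m[idx[j, 1], idx[j, 2]] + 1L
  }
  m
}

#' Channel-wise correlation matrix of binned spike counts
#'
#' Pearson product-moment correlation between the binned count vectors of
#' every channel pair (conventionally at 10 ms bins). Channels with zero
#' variance give `NA` rows/columns (reported missing, not imputed).
#'
#' @param binned channels x bins count matrix from [bin_spiketrains()].
#' @param bin_s bin width the counts were computed at, stored on the result.
#' @return a `mea_corr` object: the correlation matrix with attribute `bin_s`.
#' @export
correlation_matrix <- function(binned, bin_s = 0.010) {
  if (ncol(binned) < 2) stop("need at least 2 bins", call. = FALSE)
  v <- suppressWarnings(stats::cor(t(binned)))
  structure(v, bin_s = bin_s, class = c("mea_corr", class(v)))
}

#' Burst detection by the maximum inter-spike-interval run rule
#'
#' A burst is a maximal run of at least `min_spikes` consecutive spikes in
#' which every inter-spike interval is at most `max_isi_s`. Bursts are
#' non-overlapping and returned in time order.
#'
#' @param times numeric vector of spike timestamps (s), increasing.
#' @param max_isi_s largest in-burst inter-spike interval (s, > 0).
#' @param min_spikes minimum spikes per burst (>= 2).
#' @return tibble with `start_s`, `end_s`, `n_spikes`, one row per burst.
#' @export
detect_bursts <- function(times, max_isi_s = 0.1, min_spikes = 3) {
  stopifnot(max_isi_s > 0, min_spikes >= 2)
  empty <- tibble::tibble(start_s = double(), end_s = double(),
                          n_spikes = integer())
  n <- length(times)
  if (n < min_spikes) return(empty)
  short <- diff(times) <= max_isi_s
  r <- rle(short)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values & r$lengths >= (min_spikes - 1L))
  if (!length(keep)) return(empty)
  tibble::tibble(
    start_s = times[starts[keep]],
    end_s = times[ends[keep] + 1L],
    n_spikes = as.integer(r$lengths[keep] + 1L)
  )
}

#' Burst detection across all channels of a spike-train set
#'
#' @param spikes an `mea_spikes` object.
#' @inheritParams detect_bursts
#' @return tibble with `channel`, `start_s`, `end_s`, `n_spikes`.
#' @export
detect_bursts_all <- function(spikes, max_isi_s = 0.1, min_spikes = 3) {
  by_ch <- spikes_by_channel(spikes)
  ids <- attr(spikes, "channel_ids")
  purrr::map(seq_along(ids), function(i) {
    b <- detect_bursts(by_ch[[i]], max_isi_s, min_spikes)
    if (nrow(b)) dplyr::mutate(b, channel = ids[i], .before = 1) else NULL
  }) |>
    purrr::compact() |>
    dplyr::bind_rows()
}

#' Five-number box summary with the 1.5 IQR whisker rule
#'
#' Quartiles are computed by linear interpolation between order statistics.
#' Whiskers extend from the box edges by 1.5 times the inter-quartile range,
#' clipped to the observed data range; values beyond the whiskers are
#' outliers.
#'
#' @param values numeric vector with at least one finite value.
#' @return list of class `box_summary` with `median`, `q1`, `q3`, `iqr`,
#'   `whisker_low`, `whisker_high`, `outliers`, `n`.
#' @export
box_summary <- function(values) {
  values <- values[is.finite(values)]
  if (!length(values)) stop("need at least one finite value", call. = FALSE)
  q <- unname(stats::quantile(values, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  lo <- max(q[1] - 1.5 * iqr, min(values))
  hi <- min(q[3] + 1.5 * iqr, max(values))
  structure(list(median = q[2], q1 = q[1], q3 = q[3], iqr = iqr,
                 whisker_low = lo, whisker_high = hi,
                 outliers = values[values < lo | values > hi],
                 n = length(values)),
            class = "box_summary")
}

#' @export
print.box_summary <- function(x, ...) {
  cat(sprintf("<box_summary> n=%d median=%g [Q1 %g, Q3 %g] whiskers [%g, %g], %d outlier(s)\n",
              x$n, x$median, x$q1, x$q3, x$whisker_low, x$whisker_high,
              length(x$outliers)))
  invisible(x)
}

#' Join per-channel values onto electrode coordinates
#'
#' @param rates tibble with `channel` and at least one value column (e.g.
#'   from [firing_rates()]).
#' @param layout an `mea_layout` whose channel map covers every channel in
#'   `rates`.
#' @return tibble with `electrode_id`, `x_um`, `y_um`, `well_id` and the
#'   value columns of `rates`, one row per layout electrode.
#' @export
firing_map <- function(rates, layout) {
  stopifnot("channel" %in% names(rates))
  unmapped <- setdiff(rates$channel, layout$channel)
  if (length(unmapped)) {
    stop(sprintf("channel(s) %s not present in the layout channel map",
                 paste(unmapped, collapse = ", ")), call. = FALSE)
  }
  dplyr::left_join(
    tibble::as_tibble(layout)[, c("electrode_id", "x_um", "y_um", "well_id",
                                  "channel")],
    tibble::as_tibble(rates), by = "channel")
}
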