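# Calcium fluorescence analysis: dF/F0 normalisation of ROI-mean traces,
# event (culture-wide burst) detection, LFP extraction from the wide-band
# recording, and first-edge alignment of the two modalities.

#' Construct a fluorescence trace
#'
#' @param f per-frame ROI-mean intensities (arbitrary units), finite.
#' @param frame_rate_hz acquisition frame rate (Hz), conventionally 100 fps.
#' @param t0 start time (s).
#' @return a tibble of class `mea_fluor` with columns `time_s`, `f` and
#'   attributes `frame_rate_hz`, `t0`.
#' @export
fluorescence_trace <- function(f, frame_rate_hz = 100, t0 = 0) {
  if (frame_rate_hz <= 0) stop("frame_rate_hz must be > 0", call. = FALSE)
  if (!all(is.finite(f))) stop("intensities must be finite", call. = FALSE)
  df <- tibble::tibble(time_s = t0 + (seq_along(f) - 1) / frame_rate_hz, f = f)
  structure(df, class = c("mea_fluor", class(df)),
            frame_rate_hz = frame_rate_hz, t0 = t0)
}

#' Read / write a fluorescence trace CSV (columns `time_s`, `intensity`)
#'
#' @param trace an `mea_fluor` object.
#' @param path CSV path.
#' @return `path` (write) or an `mea_fluor` (read).
#' @export
write_fluorescence_csv <- function(trace, path) {
  readr::write_csv(tibble::tibble(time_s = trace$time_s, intensity = trace$f),
                   path)
  invisible(path)
}

#' @rdname write_fluorescence_csv
#' @export
read_fluorescence_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("time_s", "intensity") %in% names(df))) {
    stop("fluorescence CSV needs columns time_s and intensity", call. = FALSE)
  }
  dt <- diff(df$time_s)
  rate <- if (length(dt)) 1 / stats::median(dt) else 100
  fluorescence_trace(df$intensity, frame_rate_hz = rate, t0 = df$time_s[1])
}

#' Baseline fluorescence F0
#'
#' `"initial"` (default) averages the first second of frames — the
#' operational reading of "initial fluorescence intensity"; `"percentile"`
#' takes the 10th percentile of the whole trace, more robust to slow drift.
#' A numeric `baseline_mode` is used directly as F0.
#'
#' @param trace an `mea_fluor`.
#' @param baseline_mode `"initial"`, `"percentile"`, or a numeric F0.
#' @return scalar F0.
#' @export
baseline_f0 <- function(trace, baseline_mode = "initial") {
  if (is.numeric(baseline_mode)) return(baseline_mode)
  rate <- attr(trace, "frame_rate_hz")
  switch(baseline_mode,
    initial = mean(trace$f[seq_len(min(length(trace$f), max(1, round(rate))))]),
    percentile = unname(stats::quantile(trace$f, 0.10, type = 7)),
    stop(sprintf("unknown baseline_mode '%s'", baseline_mode), call. = FALSE))
}

#' Normalised fluorescence change dF/F0
#'
#' `dff = (F - F0) / F0`, elementwise and dimensionless; invariant under
#' rescaling of the raw intensities.
#'
#' @param trace an `mea_fluor`.
#' @param baseline_mode see [baseline_f0()].
#' @return a tibble of class `mea_dff` with `time_s`, `dff` and attributes
#'   `frame_rate_hz`, `f0`.
#' @export
compute_dff <- function(trace, baseline_mode = "initial") {
  f0 <- baseline_f0(trace, baseline_mode)
  if (!is.finite(f0) || f0 <= 0) {
    stop(sprintf("baseline F0 = %g; dF/F0 is undefined for F0 <= 0", f0),
         call. = FALSE)
  }
  df <- tibble::tibble(time_s = trace$time_s, dff = (trace$f - f0) / f0)
  structure(df, class = c("mea_dff", class(df)),
            frame_rate_hz = attr(trace, "frame_rate_hz"), f0 = f0)
}

#' Detect calcium events by upward threshold crossing
#'
#' An event onset is a sample crossing the threshold from below; onsets
#' closer than `min_separation_s` to the previous accepted onset are merged
#' into it. Works on any uniformly sampled series given as a frame with
#' `time_s` and a value column (`dff`, `f` or `value`).
#'
#' @param dff an `mea_dff` (or compatible frame).
#' @param threshold onset threshold on the series values (> 0).
#' @param min_separation_s minimum separation between onsets (s).
#' @return tibble with `onset_s`, one row per event.
#' @export
detect_calcium_events <- function(dff, threshold = 0.2, min_separation_s = 1) {
  stopifnot(threshold > 0)
  v <- dff[["dff"]] %||% dff[["f"]] %||% dff[["value"]]
  if (is.null(v)) stop("no value column (dff/f/value) found", call. = FALSE)
  t <- dff$time_s
  up <- which(v[-1] >= threshold & v[-length(v)] < threshold) + 1L
  if (!length(up)) return(tibble::tibble(onset_s = double()))
  keep <- up[1]
  last <- t[up[1]]
  for (i in up[-1]) {
    if (t[i] - last >= min_separation_s) {
      keep <- c(keep, i)
      last <- t[i]
    }
  }
  tibble::tibble(onset_s = t[keep])
}

#' Extract the local field potential band from a recording
#'
#' Zero-phase Butterworth low-pass (default 100 Hz cutoff, order 3) followed
#' by decimation to `decimate_to_hz` (default 1 kHz, kept at least 2.5x the
#' cutoff).
#'
#' @param recording a wide-band `mea_recording`.
#' @param cutoff_hz low-pass cutoff (Hz), below Nyquist.
#' @param order filter order.
#' @param decimate_to_hz target rate after decimation; `NULL` disables
#'   decimation.
#' @return an `mea_recording` containing the LFP band.
#' @export
extract_lfp <- function(recording, cutoff_hz = 100, order = 3,
                        decimate_to_hz = 1000) {
  stopifnot(inherits(recording, "mea_recording"))
  rate <- recording$rate
  if (cutoff_hz >= rate / 2) {
    stop(sprintf("cutoff %g Hz is not below Nyquist %g Hz", cutoff_hz, rate / 2),
         call. = FALSE)
  }
  bf <- signal::butter(order, cutoff_hz / (rate / 2), type = "low")
  # the low-pass transient scales with rate/cutoff, so pad accordingly
  n_pad <- 3L * as.integer(ceiling(rate / cutoff_hz))
  filt1 <- function(x) {
    padded <- reflect_pad(x, n_pad)
    y <- as.numeric(signal::filter(bf, padded$x))
    y <- rev(as.numeric(signal::filter(bf, rev(y))))
    if (padded$pad > 0) y[(padded$pad + 1L):(padded$pad + length(x))] else y
  }
  out <- recording
  out$signal <- t(apply(recording$signal, 1, filt1))
  if (ncol(recording$signal) == 1L) out$signal <- t(out$signal)
  if (!is.null(decimate_to_hz)) {
    decimate_to_hz <- max(decimate_to_hz, 2.5 * cutoff_hz)
    step <- max(1L, floor(rate / decimate_to_hz))
    idx <- seq(1L, ncol(out$signal), by = step)
    out$signal <- out$signal[, idx, drop = FALSE]
    out$rate <- rate / step
  }
  out
}

first_edge_time <- function(t, v, edge_fraction) {
  peak <- max(v)
  if (!is.finite(peak) || peak <= 0) return(NA_real_)
  level <- edge_fraction * peak
  idx <- which(v[-1] >= level & v[-length(v)] < level)
  if (!length(idx)) return(NA_real_)
  i <- idx[1]
  # linear interpolation between the straddling samples
  t[i] + (level - v[i]) / (v[i + 1] - v[i]) * (t[i + 1] - t[i])
}

#' First-edge lag between two series
#'
#' The first edge of a series is its first upward crossing of
#' `edge_fraction` times its own peak, linearly interpolated between
#' samples. The lag is `t_edge(a) - t_edge(b)`: positive when `a` rises
#' later. Used to align a calcium transient and the concurrent LFP event.
#'
#' @param series_a,series_b frames with `time_s` and a value column
#'   (`dff`/`f`/`value`), each containing at least one upward crossing.
#' @param edge_fraction edge level as a fraction of each series' peak
#'   (default 0.5).
#' @return lag in seconds.
#' @export
first_edge_align <- function(series_a, series_b, edge_fraction = 0.5) {
  stopifnot(edge_fraction > 0, edge_fraction <= 1)
  get_v <- function(s) s[["dff"]] %||% s[["f"]] %||% s[["value"]]
  ta <- first_edge_time(series_a$time_s, get_v(series_a), edge_fraction)
  tb <- first_edge_time(series_b$time_s, get_v(series_b), edge_fraction)
  if (is.na(ta) || is.na(tb)) {
    stop("no upward edge found in one of the series", call. = FALSE)
  }
  ta - tb
}
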