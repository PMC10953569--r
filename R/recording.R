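# Recording container: channels x samples voltage block with acquisition
# metadata. Kept matrix-backed (a 30 kHz multichannel block is not usefully
# long-format); everything downstream of detection is tibble-based.

#' Construct a multichannel recording
#'
#' A recording holds a channels-by-samples matrix of voltages in microvolts
#' together with its sampling rate, start time, channel identifiers and the
#' raw-unit-to-microvolt scale factor it was loaded with.
#'
#' @param signal numeric matrix, channels x samples, in uV.
#' @param rate sampling frequency in Hz (> 0).
#' @param t0 recording start time in seconds (default 0).
#' @param channel_ids ordered channel identifiers; default `0:(nrow-1)`.
#' @param scale raw-unit to uV conversion factor the signal was scaled by.
#' @return An object of class `mea_recording`.
#' @export
new_recording <- function(signal, rate, t0 = 0, channel_ids = NULL, scale = 1) {
  if (!is.matrix(signal)) signal <- matrix(signal, nrow = 1L)
  storage.mode(signal) <- "double"
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0) {
    stop("`rate` must be a single positive number", call. = FALSE)
  }
  if (is.null(channel_ids)) channel_ids <- seq_len(nrow(signal)) - 1L
  if (length(channel_ids) != nrow(signal)) {
    stop("`channel_ids` length must match the number of channels", call. = FALSE)
  }
  if (anyDuplicated(channel_ids)) stop("`channel_ids` must be unique", call. = FALSE)
  if (ncol(signal) > 0 && !all(is.finite(signal))) {
    stop("recording contains non-finite values", call. = FALSE)
  }
  structure(
    list(signal = signal, rate = as.numeric(rate), t0 = as.numeric(t0),
         channel_ids = channel_ids, scale = as.numeric(scale)),
    class = "mea_recording"
  )
}

#' @export
print.mea_recording <- function(x, ...) {
  cat(sprintf("<mea_recording> %d channel(s) x %d samples @ %g Hz (%.3f s), t0 = %g s\n",
              nrow(x$signal), ncol(x$signal), x$rate,
              ncol(x$signal) / x$rate, x$t0))
  invisible(x)
}

#' Recording duration in seconds
#' @param recording an `mea_recording`.
#' @return duration in seconds (samples / rate).
#' @export
rec_duration <- function(recording) ncol(recording$signal) / recording$rate

#' @export
as_tibble.mea_recording <- function(x, ...) {
  n <- ncol(x$signal)
  tibble::tibble(
    channel = rep(x$channel_ids, each = n),
    time_s = rep(seq_len(n) - 1L, times = nrow(x$signal)) / x$rate,
    uv = as.vector(t(x$signal))
  )
}

#' Extract a time segment of a recording
#'
#' Returns the samples in `[start_s, end_s)` (recording-relative seconds) as a
#' new recording whose `t0` is advanced by `start_s`. Sample indices are
#' obtained by `round(t * rate)`, so the returned duration equals
#' `end_s - start_s` to within one sample.
#'
#' @param recording an `mea_recording`.
#' @param start_s,end_s segment bounds in seconds, `0 <= start_s < end_s <= duration`.
#' @return an `mea_recording` covering the requested window.
#' @export
segment <- function(recording, start_s, end_s) {
  stopifnot(inherits(recording, "mea_recording"))
  dur <- rec_duration(recording)
  if (!is.finite(start_s) || !is.finite(end_s) || start_s < 0 ||
      end_s > dur + 0.5 / recording$rate || start_s >= end_s) {
    stop(sprintf("segment bounds [%g, %g) out of range for duration %g s",
                 start_s, end_s, dur), call. = FALSE)
  }
  i0 <- round(start_s * recording$rate)
  i1 <- min(round(end_s * recording$rate), ncol(recording$signal))
  new_recording(recording$signal[, (i0 + 1L):i1, drop = FALSE],
                rate = recording$rate,
                t0 = recording$t0 + start_s,
                channel_ids = recording$channel_ids,
                scale = recording$scale)
}

#' Split a recording into periodic windows
#'
#' Convenience for protocols that analyse the first `window_s` seconds of
#' every `period_s` (for example the first 12 minutes of every hour in a 24 h
#' recording).
#'
#' @param recording an `mea_recording`.
#' @param period_s period between window starts (s).
#' @param window_s window length (s), `window_s <= period_s`.
#' @return list of `mea_recording` segments, one per complete period.
#' @export
segment_periodic <- function(recording, period_s, window_s) {
  stopifnot(window_s > 0, window_s <= period_s)
  dur <- rec_duration(recording)
  starts <- seq(0, dur - window_s, by = period_s)
  lapply(starts, function(s) segment(recording, s, s + window_s))
}
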