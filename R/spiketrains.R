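# Spike-train and cutout containers. Spike trains are tidy tibbles
# (channel, time_s) carrying duration and the full channel roster as
# attributes so that silent channels are not lost.

#' Construct a spike-train set
#'
#' @param events data frame with columns `channel` and `time_s` (seconds,
#'   recording-relative). May have zero rows.
#' @param duration recording duration in seconds (> 0 unless empty).
#' @param channel_ids full ordered channel roster, including silent channels.
#' @return A tibble of class `mea_spikes` with attributes `duration` and
#'   `channel_ids`; rows sorted by channel then time.
#' @export
new_spike_trains <- function(events, duration, channel_ids) {
  events <- tibble::as_tibble(events)
  if (!all(c("channel", "time_s") %in% names(events))) {
    stop("`events` needs columns `channel` and `time_s`", call. = FALSE)
  }
  if (nrow(events) > 0) {
    if (any(events$time_s < 0 | events$time_s > duration)) {
      stop("spike timestamps must lie in [0, duration]", call. = FALSE)
    }
    if (!all(events$channel %in% channel_ids)) {
      stop("spike events reference channels outside `channel_ids`", call. = FALSE)
    }
    events <- dplyr::arrange(events, .data$channel, .data$time_s)
    dup <- events |>
      dplyr::group_by(.data$channel) |>
      dplyr::summarise(bad = any(diff(.data$time_s) <= 0), .groups = "drop")
    if (any(dup$bad)) {
      stop("timestamps must be strictly increasing within each channel", call. = FALSE)
    }
  }
  structure(events, class = c("mea_spikes", class(events)),
            duration = as.numeric(duration), channel_ids = channel_ids)
}

#' @export
print.mea_spikes <- function(x, ...) {
  cat(sprintf("<mea_spikes> %d events on %d channel(s), duration %g s\n",
              nrow(x), length(attr(x, "channel_ids")), attr(x, "duration")))
  NextMethod()
}

spikes_by_channel <- function(spikes) {
  ids <- attr(spikes, "channel_ids")
  out <- split(spikes$time_s, factor(spikes$channel, levels = ids))
  lapply(out, as.numeric)
}

#' Write spike timestamps to CSV
#'
#' Columns `channel`, `time_s`; silent channels are recorded in the companion
#' attributes only, not in the CSV body.
#'
#' @param spikes an `mea_spikes` object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_spikes_csv <- function(spikes, path) {
  readr::write_csv(tibble::as_tibble(spikes)[, c("channel", "time_s")], path)
  invisible(path)
}

#' Construct a cutout set
#'
#' Waveform snippets aligned on the detection extremum: each snippet has
#' `pre_samples + post_samples + 1` samples and its alignment sample (index
#' `pre_samples + 1`) is the event extremum in the detection polarity.
#'
#' @param snippets events x window numeric matrix (uV).
#' @param events tibble with `channel`, `time_s`, `sample` (1-based index into
#'   the source recording) for each snippet row.
#' @param pre_samples,post_samples window extent around the alignment sample.
#' @param rate sampling rate of the source recording (Hz).
#' @return An object of class `mea_cutouts`.
#' @export
new_cutouts <- function(snippets, events, pre_samples, post_samples, rate) {
  if (!is.matrix(snippets)) snippets <- matrix(snippets, nrow = length(snippets) > 0)
  if (nrow(snippets) != nrow(events)) {
    stop("one metadata row per snippet required", call. = FALSE)
  }
  if (nrow(snippets) > 0 && ncol(snippets) != pre_samples + post_samples + 1L) {
    stop("snippet length must equal pre_samples + post_samples + 1", call. = FALSE)
  }
  structure(
    list(snippets = snippets, events = tibble::as_tibble(events),
         pre_samples = as.integer(pre_samples),
         post_samples = as.integer(post_samples), rate = rate),
    class = "mea_cutouts"
  )
}

#' @export
print.mea_cutouts <- function(x, ...) {
  cat(sprintf("<mea_cutouts> %d snippet(s) of %d samples (pre %d / post %d) @ %g Hz\n",
              nrow(x$snippets), ncol(x$snippets), x$pre_samples,
              x$post_samples, x$rate))
  invisible(x)
}

#' @rdname tidy_mea
#' @export
tidy.mea_cutouts <- function(x, ...) {
  if (nrow(x$snippets) == 0) {
    return(tibble::tibble(event = integer(), channel = integer(),
                          time_s = double(), lag_s = double(), uv = double()))
  }
  w <- ncol(x$snippets)
  lag <- (seq_len(w) - x$pre_samples - 1L) / x$rate
  tibble::tibble(
    event = rep(seq_len(nrow(x$snippets)), each = w),
    channel = rep(x$events$channel, each = w),
    time_s = rep(x$events$time_s, each = w),
    lag_s = rep(lag, times = nrow(x$snippets)),
    uv = as.vector(t(x$snippets))
  )
}
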