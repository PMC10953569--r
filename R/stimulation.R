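# Stimulation protocol compilers. Protocols are specified as pulse-train
# parameters and compiled into flat, validated event timelines
# (t_on_s, t_off_s, level) ready for export or hardware drivers.

#' Pulse-train specification
#'
#' Electrical mode describes trains of biphasic pulses (positive phase then
#' negative phase, each `phase_us` long, immediate transition); optical mode
#' describes on/off light pulses at a duty cycle. The reference protocols
#' are 1 s trains of 20 Hz biphasic pulses with 400 us phases (electrical)
#' and 1 s trains every 5 s of 40 Hz pulses at 20% duty cycle (optical).
#'
#' @param pulse_rate_hz pulses per second within a train.
#' @param train_duration_s train length (s); `pulse_rate_hz *
#'   train_duration_s >= 1`.
#' @param inter_train_period_s period between train starts (s).
#' @param n_trains number of trains.
#' @param mode `"biphasic_electrical"` or `"optical"`.
#' @param phase_us electrical per-phase duration (us); both phases must fit
#'   in one pulse period.
#' @param amplitude_mv electrical amplitude command (mV); phases are
#'   `+amplitude_mv` then `-amplitude_mv`.
#' @param duty_cycle optical on-fraction of each pulse period, in (0, 1].
#' @return a list of class `pulse_train_spec`.
#' @export
pulse_train_spec <- function(pulse_rate_hz, train_duration_s = 1,
                             inter_train_period_s = 5, n_trains = 1,
                             mode = c("biphasic_electrical", "optical"),
                             phase_us = 400, amplitude_mv = 700,
                             duty_cycle = 0.2) {
  mode <- match.arg(mode)
  if (pulse_rate_hz <= 0 || train_duration_s <= 0) {
    stop("pulse rate and train duration must be > 0", call. = FALSE)
  }
  if (pulse_rate_hz * train_duration_s < 1) {
    stop("a train must contain at least one pulse", call. = FALSE)
  }
  if (inter_train_period_s < train_duration_s) {
    stop("inter_train_period_s must be >= train_duration_s", call. = FALSE)
  }
  if (mode == "biphasic_electrical" && 2 * phase_us > 1e6 / pulse_rate_hz) {
    stop(sprintf(
      "two %g us phases exceed the %g us pulse period at %g Hz",
      phase_us, 1e6 / pulse_rate_hz, pulse_rate_hz), call. = FALSE)
  }
  if (mode == "optical" && (duty_cycle <= 0 || duty_cycle > 1)) {
    stop("duty_cycle must be in (0, 1]", call. = FALSE)
  }
  structure(list(pulse_rate_hz = pulse_rate_hz,
                 train_duration_s = train_duration_s,
                 inter_train_period_s = inter_train_period_s,
                 n_trains = as.integer(n_trains), mode = mode,
                 phase_us = phase_us, amplitude_mv = amplitude_mv,
                 duty_cycle = duty_cycle),
            class = "pulse_train_spec")
}

new_timeline <- function(events, total_duration_s, target, mode) {
  events <- tibble::as_tibble(events)
  structure(events, class = c("mea_timeline", class(events)),
            total_duration_s = total_duration_s, target = target, mode = mode)
}

#' @export
print.mea_timeline <- function(x, ...) {
  cat(sprintf("<mea_timeline> %s: %d interval(s) over %g s, target %s\n",
              attr(x, "mode"), nrow(x), attr(x, "total_duration_s"),
              attr(x, "target")))
  NextMethod()
}

pulse_starts <- function(spec) {
  # pulses anchored at the train start with period 1/rate; partial trailing
  # pulses dropped
  n_pulses <- floor(spec$pulse_rate_hz * spec$train_duration_s + 1e-9)
  train_t0 <- (seq_len(spec$n_trains) - 1L) * spec$inter_train_period_s
  pulse_t <- (seq_len(n_pulses) - 1L) / spec$pulse_rate_hz
  list(starts = as.vector(outer(pulse_t, train_t0, `+`)),
       n_pulses = n_pulses, train_t0 = train_t0)
}

#' Compile a biphasic electrical pulse-train protocol
#'
#' Each pulse is a positive phase immediately followed by a negative phase,
#' both `phase_us` long, at levels `+amplitude_mv` and `-amplitude_mv`.
#'
#' @param spec a [pulse_train_spec()] with mode `"biphasic_electrical"`.
#' @param target stimulation electrode identifier.
#' @return an `mea_timeline` tibble (`t_on_s`, `t_off_s`, `level`).
#' @export
compile_biphasic <- function(spec, target = "stim_0") {
  stopifnot(inherits(spec, "pulse_train_spec"))
  if (spec$mode != "biphasic_electrical") {
    stop("spec mode must be 'biphasic_electrical'", call. = FALSE)
  }
  p <- pulse_starts(spec)
  ph <- spec$phase_us * 1e-6
  ev <- tibble::tibble(
    t_on_s = as.vector(rbind(p$starts, p$starts + ph)),
    t_off_s = as.vector(rbind(p$starts + ph, p$starts + 2 * ph)),
    level = rep(c(spec$amplitude_mv, -spec$amplitude_mv), length(p$starts))
  )
  total <- (spec$n_trains - 1L) * spec$inter_train_period_s + spec$train_duration_s
  new_timeline(ev, total, target, spec$mode)
}

#' Compile an optical pulse-train protocol
#'
#' Within each train, pulses repeat at `pulse_rate_hz` with on-time
#' `duty_cycle / pulse_rate_hz`; level 1 denotes light on.
#'
#' @param spec a [pulse_train_spec()] with mode `"optical"`.
#' @param target optical site identifier (e.g. a well).
#' @return an `mea_timeline` tibble.
#' @export
compile_optical <- function(spec, target = "well_0") {
  stopifnot(inherits(spec, "pulse_train_spec"))
  if (spec$mode != "optical") stop("spec mode must be 'optical'", call. = FALSE)
  p <- pulse_starts(spec)
  on_time <- spec$duty_cycle / spec$pulse_rate_hz
  ev <- tibble::tibble(t_on_s = p$starts, t_off_s = p$starts + on_time,
                       level = 1)
  total <- (spec$n_trains - 1L) * spec$inter_train_period_s + spec$train_duration_s
  new_timeline(ev, total, target, spec$mode)
}

#' Number of trains fitting in a total protocol duration
#'
#' @param total_s total protocol duration (s).
#' @param inter_train_period_s period between train starts (s).
#' @return `floor(total_s / inter_train_period_s)`.
#' @export
n_trains_in <- function(total_s, inter_train_period_s) {
  as.integer(floor(total_s / inter_train_period_s + 1e-9))
}

#' Export a timeline as a plain event table
#'
#' @param timeline an `mea_timeline`.
#' @param path optional CSV or JSON path to write (by extension).
#' @return tibble with `t_on_s`, `t_off_s`, `level`.
#' @export
timeline_to_events <- function(timeline, path = NULL) {
  ev <- tibble::tibble(t_on_s = timeline$t_on_s, t_off_s = timeline$t_off_s,
                       level = timeline$level)
  if (!is.null(path)) {
    if (grepl("\\.json$", path, ignore.case = TRUE)) {
      jsonlite::write_json(ev, path, digits = NA)
    } else {
      readr::write_csv(ev, path)
    }
  }
  ev
}

#' Read / write a pulse-train protocol as YAML
#'
#' The YAML keys mirror the [pulse_train_spec()] fields.
#'
#' @param spec a `pulse_train_spec`.
#' @param path YAML file path.
#' @return `path` (write) or a `pulse_train_spec` (read).
#' @export
write_protocol_yaml <- function(spec, path) {
  stopifnot(inherits(spec, "pulse_train_spec"))
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

#' @rdname write_protocol_yaml
#' @export
read_protocol_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pulse_train_spec, raw)
}

#' Validate a stimulation timeline
#'
#' Checks that intervals are well-formed (`t_on < t_off`), time-ordered,
#' non-overlapping, and contained in the total duration.
#'
#' @param timeline an `mea_timeline` (or a frame with the three columns).
#' @return list with `ok` (logical) and `violations` (tibble of offending
#'   interval indices and reasons).
#' @export
validate_timeline <- function(timeline) {
  ev <- tibble::as_tibble(timeline)
  total <- attr(timeline, "total_duration_s") %||% Inf
  v <- list()
  bad_span <- which(ev$t_on_s >= ev$t_off_s)
  if (length(bad_span)) v[[length(v) + 1]] <-
    tibble::tibble(index = bad_span, reason = "t_on >= t_off")
  if (nrow(ev) > 1) {
    overlap <- which(ev$t_on_s[-1] < ev$t_off_s[-nrow(ev)] - 1e-12)
    if (length(overlap)) v[[length(v) + 1]] <-
      tibble::tibble(index = overlap + 1L, reason = "overlaps previous interval")
    unordered <- which(diff(ev$t_on_s) < 0)
    if (length(unordered)) v[[length(v) + 1]] <-
      tibble::tibble(index = unordered + 1L, reason = "out of time order")
  }
  beyond <- which(ev$t_off_s > total + 1e-12)
  if (length(beyond)) v[[length(v) + 1]] <-
    tibble::tibble(index = beyond, reason = "beyond total duration")
  violations <- if (length(v)) dplyr::bind_rows(v) else
    tibble::tibble(index = integer(), reason = character())
  list(ok = nrow(violations) == 0, violations = violations)
}
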