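# Flat-binary recording dialect: channel-interleaved little-endian int16
# frames with a JSON sidecar (rate, n_channels, scale, t0). Matches common
# acquisition-board exports while staying self-describing.

#' Read a raw binary recording
#'
#' Reads a channel-interleaved little-endian int16 file. Metadata comes from
#' `meta` (a list) or, when `meta` is `NULL`, from the JSON sidecar
#' `<path>.json`. Required fields: `rate`, `n_channels`, `scale`; optional
#' `t0` (default 0) and `channel_ids`. Sample values are multiplied by
#' `scale` to give microvolts.
#'
#' @param path binary file path.
#' @param meta metadata list, or `NULL` to read `<path>.json`.
#' @return an [new_recording()] object.
#' @export
read_raw_binary <- function(path, meta = NULL) {
  if (is.null(meta)) {
    sidecar <- paste0(path, ".json")
    if (!file.exists(sidecar)) {
      stop(sprintf("no metadata supplied and sidecar '%s' not found", sidecar),
           call. = FALSE)
    }
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  }
  for (field in c("rate", "n_channels", "scale")) {
    if (is.null(meta[[field]])) {
      stop(sprintf("metadata field '%s' is missing", field), call. = FALSE)
    }
  }
  n_ch <- as.integer(meta$n_channels)
  bytes <- file.size(path)
  if (is.na(bytes)) stop(sprintf("cannot read '%s'", path), call. = FALSE)
  frame_bytes <- n_ch * 2L
  if (bytes %% frame_bytes != 0) {
    stop(sprintf(
      "malformed file '%s': %d bytes is not divisible by %d (= %d channels x 2 bytes); expected a whole number of frames",
      path, bytes, frame_bytes, n_ch), call. = FALSE)
  }
  n_samples <- bytes %/% frame_bytes
  raw <- readBin(path, what = "integer", n = n_ch * n_samples, size = 2L,
                 signed = TRUE, endian = "little")
  sig <- matrix(as.numeric(raw) * meta$scale, nrow = n_ch)
  ids <- meta$channel_ids %||% (seq_len(n_ch) - 1L)
  new_recording(sig, rate = meta$rate, t0 = meta$t0 %||% 0,
                channel_ids = ids, scale = meta$scale)
}

#' Write a recording in the raw binary dialect
#'
#' Values are divided by `recording$scale`, rounded to the nearest integer and
#' written as channel-interleaved little-endian int16, alongside a JSON
#' sidecar `<path>.json` holding rate, channel count, scale, t0 and channel
#' identifiers.
#'
#' @param recording an `mea_recording`.
#' @param path output binary path.
#' @return `path`, invisibly.
#' @export
write_raw_binary <- function(recording, path) {
  stopifnot(inherits(recording, "mea_recording"))
  raw <- as.integer(round(as.vector(recording$signal) / recording$scale))
  if (length(raw) && (max(raw) > 32767L || min(raw) < -32768L)) {
    stop("scaled values exceed the int16 range; increase `scale`", call. = FALSE)
  }
  writeBin(raw, path, size = 2L, endian = "little")
  jsonlite::write_json(
    list(rate = recording$rate, n_channels = nrow(recording$signal),
         scale = recording$scale, t0 = recording$t0,
         channel_ids = recording$channel_ids, dtype = "int16",
         byte_order = "little"),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
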