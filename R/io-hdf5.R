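# HDF5 container. One group per object type, tagged with a schema-version
# attribute so future layout changes stay detectable:
#   /recording: signal (channels x samples), rate, t0, scale, channel_ids
#   /spikes:    duration, channel_ids, ch_<id> timestamp vectors
SCHEMA_RECORDING <- "meapipe-recording-1"
SCHEMA_SPIKES <- "meapipe-spikes-1"

h5_tag_group <- function(path, group, tag) {
  fid <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(fid), add = TRUE)
  gid <- rhdf5::H5Gopen(fid, group)
  on.exit(rhdf5::H5Gclose(gid), add = TRUE, after = FALSE)
  rhdf5::h5writeAttribute(tag, gid, "schema_version")
}

h5_check_tag <- function(path, group, expected) {
  at <- rhdf5::h5readAttributes(path, group)
  tag <- at$schema_version
  if (is.null(tag) || !identical(as.character(tag), expected)) {
    stop(sprintf("'%s' group '%s' has schema tag '%s'; this reader expects '%s'",
                 path, group, if (is.null(tag)) "<none>" else tag, expected),
         call. = FALSE)
  }
}

#' Write a recording or spike-train set to an HDF5 container
#'
#' Round-trip safe: [read_hdf5()] on the written file reproduces the object
#' bit-exactly for integer-valued fields and to machine precision for floats.
#' An existing file at `path` is overwritten.
#'
#' @param x an `mea_recording` or `mea_spikes` object.
#' @param path output `.h5` path.
#' @return `path`, invisibly.
#' @export
write_hdf5 <- function(x, path) {
  if (file.exists(path)) file.remove(path)
  ok <- rhdf5::h5createFile(path)
  if (!isTRUE(ok)) stop(sprintf("cannot create '%s'", path), call. = FALSE)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  if (inherits(x, "mea_recording")) {
    rhdf5::h5createGroup(path, "recording")
    rhdf5::h5write(x$signal, path, "recording/signal")
    rhdf5::h5write(x$rate, path, "recording/rate")
    rhdf5::h5write(x$t0, path, "recording/t0")
    rhdf5::h5write(x$scale, path, "recording/scale")
    rhdf5::h5write(as.character(x$channel_ids), path, "recording/channel_ids")
    h5_tag_group(path, "recording", SCHEMA_RECORDING)
  } else if (inherits(x, "mea_spikes")) {
    rhdf5::h5createGroup(path, "spikes")
    rhdf5::h5write(attr(x, "duration"), path, "spikes/duration")
    ids <- attr(x, "channel_ids")
    rhdf5::h5write(as.character(ids), path, "spikes/channel_ids")
    by_ch <- spikes_by_channel(x)
    for (i in seq_along(ids)) {
      rhdf5::h5write(by_ch[[i]], path, paste0("spikes/ch_", ids[i]))
    }
    h5_tag_group(path, "spikes", SCHEMA_SPIKES)
  } else {
    stop("`x` must be an mea_recording or mea_spikes object", call. = FALSE)
  }
  invisible(path)
}

#' Read an object back from an HDF5 container
#'
#' @param path an `.h5` file written by [write_hdf5()].
#' @return the stored `mea_recording` or `mea_spikes` object.
#' @export
read_hdf5 <- function(path) {
  if (!file.exists(path)) stop(sprintf("'%s' not found", path), call. = FALSE)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  groups <- rhdf5::h5ls(path, recursive = FALSE)$name
  if ("recording" %in% groups) {
    h5_check_tag(path, "recording", SCHEMA_RECORDING)
    sig <- rhdf5::h5read(path, "recording/signal")
    if (!is.matrix(sig)) sig <- matrix(sig, nrow = 1L)
    ids <- as.character(rhdf5::h5read(path, "recording/channel_ids"))
    ids_num <- suppressWarnings(as.numeric(ids))
    if (!anyNA(ids_num)) ids <- ids_num
    new_recording(sig,
                  rate = as.numeric(rhdf5::h5read(path, "recording/rate")),
                  t0 = as.numeric(rhdf5::h5read(path, "recording/t0")),
                  channel_ids = ids,
                  scale = as.numeric(rhdf5::h5read(path, "recording/scale")))
  } else if ("spikes" %in% groups) {
    h5_check_tag(path, "spikes", SCHEMA_SPIKES)
    ids <- as.character(rhdf5::h5read(path, "spikes/channel_ids"))
    ids_num <- suppressWarnings(as.numeric(ids))
    if (!anyNA(ids_num)) ids <- ids_num
    times <- lapply(ids, function(id) {
      as.numeric(rhdf5::h5read(path, paste0("spikes/ch_", id)))
    })
    events <- tibble::tibble(
      channel = rep(ids, lengths(times)),
      time_s = unlist(times, use.names = FALSE) %||% numeric(0)
    )
    new_spike_trains(events,
                     duration = as.numeric(rhdf5::h5read(path, "spikes/duration")),
                     channel_ids = ids)
  } else {
    stop(sprintf("'%s' contains no recognised group (saw: %s)",
                 path, paste(groups, collapse = ", ")), call. = FALSE)
  }
}
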