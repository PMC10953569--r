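# MEA electrode layout geometry. A layout is a tibble with one row per
# electrode (electrode_id, x_um, y_um, diameter_um, well_id, channel) plus
# pitch and any dedicated stimulation-site annotations as attributes.
# Convention: um, origin at the array centroid, y up, electrode centers.

new_layout <- function(df, pitch, stim_sites = NULL) {
  df <- tibble::as_tibble(df)
  if (anyDuplicated(df[, c("x_um", "y_um")])) {
    stop("electrode positions must be unique", call. = FALSE)
  }
  if (nrow(df) > 0) {
    if (any(df$diameter_um <= 0)) stop("diameter must be > 0", call. = FALSE)
    ch <- sort(df$channel)
    if (!identical(as.integer(ch), seq_len(nrow(df)) - 1L)) {
      stop("channel map must be a bijection onto 0..N-1", call. = FALSE)
    }
  }
  structure(df, class = c("mea_layout", class(df)),
            pitch = pitch, stim_sites = stim_sites)
}

#' @export
print.mea_layout <- function(x, ...) {
  cat(sprintf("<mea_layout> %d electrode(s), pitch %g um, %d well(s)\n",
              nrow(x), attr(x, "pitch"), length(unique(x$well_id))))
  NextMethod()
}

# Near-square grid coordinates for n sites: smallest r x c grid with
# r*c >= n, extras dropped farthest-from-centre first (ties by y then x).
# The 59/128 capacities follow their conventional footprints instead.
grid_sites <- function(n, pitch) {
  nr <- floor(sqrt(n))
  nc <- ceiling(n / nr)
  while (nr * nc < n) nc <- nc + 1L
  g <- expand.grid(col = seq_len(nc), row = seq_len(nr))
  g$x <- (g$col - (nc + 1) / 2) * pitch
  g$y <- ((nr + 1) / 2 - g$row) * pitch
  drop_n <- nr * nc - n
  if (drop_n > 0) {
    ord <- order(-(g$x^2 + g$y^2), g$y, g$x)
    g <- g[-ord[seq_len(drop_n)], ]
  }
  g[order(-g$y, g$x), c("x", "y")]
}

rect_sites <- function(capacity, pitch) {
  if (capacity == 59) {
    # Commercial-compatible 60MEA footprint: 8x8 grid minus the four corners
    # minus one internal reference site (left column, mid-height).
    g <- expand.grid(col = 1:8, row = 1:8)
    g$x <- (g$col - 4.5) * pitch
    g$y <- (4.5 - g$row) * pitch
    corner <- (g$col %in% c(1, 8)) & (g$row %in% c(1, 8))
    ref <- g$col == 1 & g$row == 4
    g <- g[!(corner | ref), ]
    g[order(-g$y, g$x), c("x", "y")]
  } else if (capacity == 128) {
    # 12 x 11 grid minus the four corners.
    g <- expand.grid(col = 1:12, row = 1:11)
    g$x <- (g$col - 6.5) * pitch
    g$y <- (6 - g$row) * pitch
    corner <- (g$col %in% c(1, 12)) & (g$row %in% c(1, 11))
    g <- g[!corner, ]
    g[order(-g$y, g$x), c("x", "y")]
  } else if (capacity == 256) {
    grid_sites(256, pitch)   # exact 16 x 16
  } else if (capacity == 512) {
    grid_sites(512, pitch)   # 23 x 23 minus 17 corner-most sites
  } else {
    stop(sprintf("unsupported capacity %s; choose one of 59, 128, 256, 512",
                 capacity), call. = FALSE)
  }
}

finish_layout <- function(xy, diameter, pitch, well_id = 0L, with_stim = TRUE) {
  n <- nrow(xy)
  df <- tibble::tibble(
    electrode_id = seq_len(n) - 1L,
    x_um = xy$x, y_um = xy$y,
    diameter_um = diameter,
    well_id = rep_len(well_id, n),
    channel = seq_len(n) - 1L
  )
  stim <- NULL
  if (with_stim) {
    # Four dedicated stimulation sites just outside each grid edge
    # (non-recording annotations, mid-edge, one pitch out).
    stim <- tibble::tibble(
      stim_id = 0:3,
      x_um = c(0, max(xy$x) + pitch, 0, min(xy$x) - pitch),
      y_um = c(max(xy$y) + pitch, 0, min(xy$y) - pitch, 0)
    )
  }
  new_layout(df, pitch = pitch, stim_sites = stim)
}

#' Rectangular MEA layout
#'
#' Supported capacities: 59 (commercial-compatible 8x8 footprint: 64 sites
#' minus 4 corners minus 1 reference site, conventionally at 200 um pitch and
#' 30 um diameter), 128 (12x11 minus corners), 256 (16x16) and 512 (23x23
#' minus 17). Capacities other than 59 carry four dedicated stimulation-site
#' annotations just outside the grid edges (attribute `stim_sites`).
#'
#' @param capacity one of 59, 128, 256, 512.
#' @param pitch_um electrode centre-to-centre spacing (um, > 0).
#' @param diameter_um electrode diameter (um, > 0).
#' @return an `mea_layout` tibble.
#' @export
make_rect <- function(capacity, pitch_um = 200, diameter_um = 30) {
  if (!is.numeric(pitch_um) || pitch_um <= 0) stop("pitch must be > 0", call. = FALSE)
  if (!is.numeric(diameter_um) || diameter_um <= 0) stop("diameter must be > 0", call. = FALSE)
  xy <- rect_sites(capacity, pitch_um)
  finish_layout(xy, diameter_um, pitch_um, with_stim = capacity != 59)
}

#' Curved MEA layout
#'
#' Bends every electrode row of the rectangular layout onto a circular arc of
#' radius `1/curvature`, preserving the along-arc pitch, so that the array
#' follows a cortical curvature (about 0.35 per mm for mouse cortex). A
#' circle fit to any single row recovers the radius `1/curvature`.
#' `curvature_per_mm = 0` returns the rectangular layout unchanged.
#'
#' @param capacity as in [make_rect()].
#' @param curvature_per_mm arc curvature in 1/mm (>= 0).
#' @param pitch_um,diameter_um as in [make_rect()].
#' @return an `mea_layout` tibble.
#' @export
make_curved <- function(capacity, curvature_per_mm = 0.35, pitch_um = 200,
                        diameter_um = 30) {
  if (!is.numeric(curvature_per_mm) || curvature_per_mm < 0) {
    stop("curvature must be >= 0", call. = FALSE)
  }
  base <- make_rect(capacity, pitch_um, diameter_um)
  if (curvature_per_mm == 0) return(base)
  r_um <- 1000 / curvature_per_mm
  theta <- base$x_um / r_um               # along-arc length preserved
  out <- base
  out$x_um <- r_um * sin(theta)
  out$y_um <- base$y_um + r_um * (1 - cos(theta))  # rows bow upward
  new_layout(out, pitch = attr(base, "pitch"), stim_sites = attr(base, "stim_sites"))
}

#' Perturbed MEA layout
#'
#' Displaces every electrode of the rectangular layout by an independent
#' random offset drawn uniformly from the disk of radius `max_disp_um`
#' (reduces spatial aliasing in regular-grid sampling). The same seed always
#' produces the same layout.
#'
#' @param capacity as in [make_rect()].
#' @param max_disp_um maximum displacement (um); must satisfy
#'   `0 <= max_disp_um < pitch_um / 2` to exclude position collisions.
#' @param seed integer RNG seed.
#' @param pitch_um,diameter_um as in [make_rect()].
#' @return an `mea_layout` tibble.
#' @export
make_perturbed <- function(capacity, max_disp_um = 50, seed = 1,
                           pitch_um = 200, diameter_um = 30) {
  if (!is.numeric(max_disp_um) || max_disp_um < 0 || max_disp_um >= pitch_um / 2) {
    stop("max_disp_um must satisfy 0 <= max_disp < pitch/2", call. = FALSE)
  }
  base <- make_rect(capacity, pitch_um, diameter_um)
  if (max_disp_um == 0) return(base)
  out <- withr::with_seed(as.integer(seed), {
    n <- nrow(base)
    r <- max_disp_um * sqrt(stats::runif(n))   # uniform over the disk
    phi <- stats::runif(n, 0, 2 * pi)
    b <- base
    b$x_um <- base$x_um + r * cos(phi)
    b$y_um <- base$y_um + r * sin(phi)
    b
  })
  new_layout(out, pitch = attr(base, "pitch"), stim_sites = attr(base, "stim_sites"))
}

#' Multi-well MEA layout
#'
#' `n_wells` independent near-square electrode grids on one chip, arranged on
#' a square macro-grid of wells with centre-to-centre spacing
#' `well_spacing_um`. Channels are numbered well by well. The spacing must
#' keep every inter-well electrode distance larger than the largest
#' intra-well distance, so wells remain geometrically separable.
#'
#' @param n_wells number of wells (>= 1).
#' @param per_well_capacity electrodes per well.
#' @param well_spacing_um centre-to-centre well spacing (um).
#' @param pitch_um,diameter_um as in [make_rect()].
#' @return an `mea_layout` tibble with `well_id` in `0..n_wells-1`.
#' @export
make_multiwell <- function(n_wells = 4, per_well_capacity = 32,
                           well_spacing_um = 5000, pitch_um = 200,
                           diameter_um = 30) {
  if (!is.numeric(n_wells) || n_wells < 1) stop("n_wells must be >= 1", call. = FALSE)
  if (per_well_capacity < 1) stop("per_well_capacity must be >= 1", call. = FALSE)
  if (n_wells == 1 && per_well_capacity %in% c(59, 128, 256, 512)) {
    return(make_rect(per_well_capacity, pitch_um, diameter_um))
  }
  xy <- if (per_well_capacity %in% c(59, 128, 256, 512)) {
    rect_sites(per_well_capacity, pitch_um)
  } else {
    grid_sites(per_well_capacity, pitch_um)
  }
  wc <- ceiling(sqrt(n_wells))
  wr <- ceiling(n_wells / wc)
  centers <- expand.grid(col = seq_len(wc), row = seq_len(wr))[seq_len(n_wells), ]
  cx <- (centers$col - (wc + 1) / 2) * well_spacing_um
  cy <- ((wr + 1) / 2 - centers$row) * well_spacing_um
  if (n_wells > 1) {
    intra_max <- max(stats::dist(xy))
    gap <- well_spacing_um - (max(xy$x) - min(xy$x))
    if (gap <= intra_max) {
      stop(sprintf(
        "well_spacing_um %g leaves inter-well distance <= intra-well maximum (%g um); increase spacing",
        well_spacing_um, intra_max), call. = FALSE)
    }
  }
  parts <- lapply(seq_len(n_wells), function(w) {
    tibble::tibble(x_um = xy$x + cx[w], y_um = xy$y + cy[w], well_id = w - 1L)
  })
  df <- dplyr::bind_rows(parts)
  df$electrode_id <- seq_len(nrow(df)) - 1L
  df$diameter_um <- diameter_um
  df$channel <- seq_len(nrow(df)) - 1L
  new_layout(df[, c("electrode_id", "x_um", "y_um", "diameter_um", "well_id",
                    "channel")],
             pitch = pitch_um, stim_sites = NULL)
}

#' Fit a circle to points by algebraic least squares
#'
#' Kasa fit: solves `x^2 + y^2 + D x + E y + F = 0` in least squares. Exact
#' for points lying on a true circle.
#'
#' @param x,y point coordinates.
#' @return list with `xc`, `yc`, `radius` and `rms_residual` (RMS radial
#'   distance of the points from the fitted circle, same units as input).
#' @export
fit_circle <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  A <- cbind(x, y, 1)
  b <- -(x^2 + y^2)
  coef <- qr.solve(A, b)
  xc <- -coef[1] / 2
  yc <- -coef[2] / 2
  r <- sqrt(xc^2 + yc^2 - coef[3])
  res <- sqrt(mean((sqrt((x - xc)^2 + (y - yc)^2) - r)^2))
  list(xc = unname(xc), yc = unname(yc), radius = unname(r),
       rms_residual = unname(res))
}

#' Recover the curvature of one electrode row of a curved layout
#'
#' Groups electrodes into rows (by nearest base-grid row for curved layouts:
#' the row with the most electrodes is used by default) and circle-fits one
#' row.
#'
#' @param layout a curved `mea_layout`.
#' @param row which row to fit, counted from the top; `NULL` picks the row
#'   with the most electrodes.
#' @return fitted curvature in 1/mm.
#' @export
fit_row_curvature <- function(layout, row = NULL) {
  # layouts are constructed row-major with x increasing within a row, so a
  # new row starts wherever x decreases
  new_row <- c(TRUE, diff(layout$x_um) < 0)
  row_id <- cumsum(new_row)
  if (is.null(row)) row <- as.integer(names(which.max(table(row_id))))
  sel <- row_id == row
  if (sum(sel) < 3) stop("selected row has fewer than 3 electrodes", call. = FALSE)
  fit <- fit_circle(layout$x_um[sel], layout$y_um[sel])
  1000 / fit$radius
}

#' Write / read a layout as CSV or JSON
#'
#' Columns: `electrode_id`, `x_um`, `y_um`, `diameter_um`, `well_id`,
#' `channel`. Format chosen by file extension (`.csv` or `.json`).
#'
#' @param layout an `mea_layout`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_layout <- function(layout, path) {
  cols <- c("electrode_id", "x_um", "y_um", "diameter_um", "well_id", "channel")
  df <- tibble::as_tibble(layout)[, cols]
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(df, path, digits = NA)
  } else {
    readr::write_csv(df, path)
  }
  invisible(path)
}

#' @rdname write_layout
#' @param pitch_um pitch recorded on the loaded layout (not stored in the
#'   file; default 200).
#' @export
read_layout <- function(path, pitch_um = 200) {
  df <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    tibble::as_tibble(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    readr::read_csv(path, show_col_types = FALSE)
  }
  cols <- c("electrode_id", "x_um", "y_um", "diameter_um", "well_id", "channel")
  missing <- setdiff(cols, names(df))
  if (nrow(df) == 0 && length(names(df)) == 0) {
    df <- tibble::tibble(electrode_id = integer(), x_um = double(),
                         y_um = double(), diameter_um = double(),
                         well_id = integer(), channel = integer())
    missing <- character()
  }
  if (length(missing)) {
    stop(sprintf("layout file '%s' is missing column(s): %s",
                 path, paste(missing, collapse = ", ")), call. = FALSE)
  }
  new_layout(df[, cols], pitch = pitch_um)
}
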