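# Core domain types and I/O: tracks, spot grids, mask series.
#
# Conventions: continuous coordinates are micrometres in a right-handed x/y
# plane; times are seconds from track start; rasters are 0-based row/col with
# the world coordinate of pixel (0,0) stored alongside. Frame gaps are
# preserved, never interpolated; time differences always use true times.

#' Construct a single-cell migration track
#'
#' A track is one cell's time-ordered 2D centroid trajectory, optionally
#' carrying named per-frame scalar channels (e.g. a ratiometric calcium
#' readout or projected cell area).
#'
#' @param cell_id Opaque identifier (coerced to character).
#' @param frames Integer frame indices, 0-based, strictly increasing. Gaps are
#'   allowed and preserved.
#' @param x,y Centroid coordinates in micrometres.
#' @param times Seconds from track start; defaults to `frames * frame_interval`.
#' @param channels Named list of numeric per-frame series, each the same
#'   length as `frames`.
#' @param frame_interval Seconds per frame (default 30).
#' @return An object of class `sk_track` with fields `cell_id`, `frames`,
#'   `times`, `positions` (n x 2 matrix, columns `x`, `y`), `channels`,
#'   `frame_interval`.
#' @export
track <- function(cell_id, frames, x, y, times = NULL,
                  channels = list(), frame_interval = 30) {
  frames <- as.integer(frames)
  n <- length(frames)
  if (n < 1L) stop("track must have at least one frame")
  if (is.unsorted(frames, strictly = TRUE)) {
    stop("frames must be strictly increasing")
  }
  if (any(frames < 0L)) stop("frames must be non-negative (0-based)")
  if (is.null(times)) times <- frames * frame_interval
  times <- as.numeric(times)
  if (length(times) != n || any(times < 0) ||
      (n > 1L && is.unsorted(times, strictly = TRUE))) {
    stop("times must be non-negative, strictly increasing, one per frame")
  }
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != n || length(y) != n) stop("x/y must have one value per frame")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("positions must be finite")
  if (length(channels)) {
    if (is.null(names(channels)) || any(!nzchar(names(channels)))) {
      stop("channels must be a named list")
    }
    bad <- names(channels)[vapply(channels, length, 1L) != n]
    if (length(bad)) {
      stop("channel length mismatch: ", paste(bad, collapse = ", "))
    }
    channels <- lapply(channels, as.numeric)
  }
  structure(
    list(cell_id = as.character(cell_id), frames = frames, times = times,
         positions = cbind(x = x, y = y), channels = channels,
         frame_interval = frame_interval),
    class = "sk_track")
}

#' @export
print.sk_track <- function(x, ...) {
  cat(sprintf("<sk_track> cell %s: %d frames, %.1f min, channels: %s\n",
              x$cell_id, length(x$frames), diff(range(x$times)) / 60,
              if (length(x$channels)) paste(names(x$channels), collapse = ", ")
              else "none"))
  invisible(x)
}

#' Number of frames in a track
#' @param track An `sk_track`.
#' @return Integer frame count.
#' @export
n_frames <- function(track) length(track$frames)

#' Read tracks from a track-table CSV
#'
#' Expects columns `cell_id,frame,time_s,x_um,y_um`; any additional numeric
#' column is attached as a per-frame channel under its own name. Rows may be
#' unordered; they are sorted by frame within each cell.
#'
#' @param path CSV file path.
#' @param frame_interval Seconds per frame recorded on each track (default 30).
#' @return Named list of `sk_track`, one per `cell_id`.
#' @export
read_tracks <- function(path, frame_interval = 30) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("cell_id", "frame", "time_s", "x_um", "y_um")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  dup <- duplicated(df[c("cell_id", "frame")])
  if (any(dup)) {
    stop("duplicate (cell_id, frame) rows: ",
         paste(which(dup), collapse = ", "))
  }
  for (col in c("frame", "time_s", "x_um", "y_um")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (any(is.na(v) & !is.na(df[[col]])) || any(is.na(v))) {
      stop("non-numeric values in column ", col)
    }
    df[[col]] <- v
  }
  chan_cols <- setdiff(names(df), req)
  out <- lapply(split(df, df$cell_id), function(d) {
    d <- d[order(d$frame), , drop = FALSE]
    chans <- lapply(d[chan_cols], as.numeric)
    names(chans) <- chan_cols
    track(d$cell_id[1], d$frame, d$x_um, d$y_um, times = d$time_s,
          channels = chans, frame_interval = frame_interval)
  })
  out[order(names(out))]
}

#' Write tracks to a track-table CSV
#'
#' Inverse of [read_tracks()]: emits `cell_id,frame,time_s,x_um,y_um` plus one
#' column per channel. Round-trips losslessly up to row order.
#'
#' @param tracks A list of `sk_track` (or a single track).
#' @param path Output CSV path.
#' @export
write_tracks <- function(tracks, path) {
  if (inherits(tracks, "sk_track")) tracks <- list(tracks)
  rows <- lapply(tracks, function(tr) {
    d <- data.frame(cell_id = tr$cell_id, frame = tr$frames,
                    time_s = tr$times, x_um = tr$positions[, "x"],
                    y_um = tr$positions[, "y"], stringsAsFactors = FALSE)
    for (nm in names(tr$channels)) d[[nm]] <- tr$channels[[nm]]
    d
  })
  all_cols <- Reduce(union, lapply(rows, names))
  rows <- lapply(rows, function(d) {
    for (nm in setdiff(all_cols, names(d))) d[[nm]] <- NA_real_
    d[all_cols]
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

# ---- spot grids ------------------------------------------------------------

#' Build a square-lattice grid of stimulatory spots
#'
#' Models micro-contact-printed anti-CD3 disks: circular spots of a given
#' diameter placed on a square lattice (30 um centre-to-centre in the source
#' experiments). The lattice is centred within the extent; spot ids number
#' row-major from the lower-left corner and are stable for a given geometry.
#'
#' @param diameter Spot diameter, um (10 or 20 in the experiments modelled).
#' @param spacing Centre-to-centre spacing, um; must be >= diameter.
#' @param extent Bounding rectangle `c(xmin, ymin, xmax, ymax)` in um, or
#'   `c(width, height)` shorthand for a rectangle anchored at the origin.
#' @return An `sk_spot_grid`: fields `diameter`, `spacing`, `extent`, and
#'   `centers` (data.frame `spot_id`, `x`, `y`).
#' @export
build_spot_grid <- function(diameter, spacing, extent) {
  stopifnot(diameter > 0)
  if (spacing < diameter) stop("spacing must be >= diameter")
  if (length(extent) == 2L) extent <- c(0, 0, extent[1], extent[2])
  stopifnot(length(extent) == 4L, extent[3] > extent[1], extent[4] > extent[2])
  w <- extent[3] - extent[1]; h <- extent[4] - extent[2]
  nx <- max(1L, floor(w / spacing) + 1L)
  ny <- max(1L, floor(h / spacing) + 1L)
  if (nx == 1L && ny == 1L && (w < spacing || h < spacing)) {
    warning("extent smaller than one spacing: single-spot grid")
  }
  x0 <- extent[1] + (w - (nx - 1L) * spacing) / 2
  y0 <- extent[2] + (h - (ny - 1L) * spacing) / 2
  centers <- expand.grid(x = x0 + spacing * (seq_len(nx) - 1L),
                         y = y0 + spacing * (seq_len(ny) - 1L))
  centers <- centers[order(centers$y, centers$x), ]
  centers <- data.frame(spot_id = seq_len(nrow(centers)),
                        x = centers$x, y = centers$y)
  structure(list(diameter = diameter, spacing = spacing,
                 extent = unname(extent), centers = centers),
            class = "sk_spot_grid")
}

#' @export
print.sk_spot_grid <- function(x, ...) {
  cat(sprintf("<sk_spot_grid> %d spots, diameter %g um, spacing %g um\n",
              nrow(x$centers), x$diameter, x$spacing))
  invisible(x)
}

#' Read or write a spot grid as JSON
#'
#' The JSON dialect stores `diameter_um`, `spacing_um` and `extent_um`; the
#' lattice centres are re-derived deterministically on read.
#'
#' @param grid An `sk_spot_grid`.
#' @param path JSON file path.
#' @return `read_spot_grid` returns an `sk_spot_grid`.
#' @export
write_spot_grid <- function(grid, path) {
  jsonlite::write_json(list(diameter_um = grid$diameter,
                            spacing_um = grid$spacing,
                            extent_um = grid$extent),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_spot_grid
#' @export
read_spot_grid <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  build_spot_grid(j$diameter_um, j$spacing_um, j$extent_um)
}

# ---- mask series -----------------------------------------------------------

#' Construct a per-frame binary mask series
#'
#' Per-frame segmented cell footprints on a fixed raster. Pixel (row 1, col 1)
#' has its centre at world coordinate `origin`; pixel centres advance by
#' `pixel_size` along +x (columns) and +y (rows).
#'
#' @param frames Integer frame indices, strictly increasing.
#' @param masks List of logical matrices, all the same dimension.
#' @param pixel_size um per pixel (> 0).
#' @param origin World coordinate (um) of the centre of pixel (1,1),
#'   `c(x, y)`.
#' @return An `sk_mask_series`.
#' @export
mask_series <- function(frames, masks, pixel_size, origin = c(0, 0)) {
  frames <- as.integer(frames)
  stopifnot(length(frames) == length(masks), pixel_size > 0,
            length(origin) == 2L)
  if (length(frames) > 1L && is.unsorted(frames, strictly = TRUE)) {
    stop("frames must be strictly increasing")
  }
  masks <- lapply(masks, function(m) {
    if (!is.matrix(m)) stop("each mask must be a matrix")
    m <- m != 0
    m
  })
  dims <- unique(lapply(masks, dim))
  if (length(dims) > 1L) stop("all masks must share one raster shape")
  empty <- vapply(masks, function(m) !any(m), logical(1))
  structure(list(frames = frames, masks = masks, pixel_size = pixel_size,
                 origin = as.numeric(origin), empty = empty),
            class = "sk_mask_series")
}

#' @export
print.sk_mask_series <- function(x, ...) {
  d <- dim(x$masks[[1]])
  cat(sprintf("<sk_mask_series> %d frames, %dx%d px at %g um/px (%d empty)\n",
              length(x$frames), d[1], d[2], x$pixel_size, sum(x$empty)))
  invisible(x)
}

#' Write / read a mask series as plain text
#'
#' Serializes foreground pixels as a long CSV (`frame,row,col`, 1-based) with
#' a JSON sidecar (`<stem>.json`) recording raster shape, pixel size and
#' origin. A text dialect is used in place of multi-page TIFF so mask fixtures
#' stay human-readable and dependency-free.
#'
#' @param ms An `sk_mask_series`.
#' @param path CSV path; the sidecar is written next to it.
#' @return `read_masks` returns an `sk_mask_series`.
#' @export
write_masks <- function(ms, path) {
  px <- do.call(rbind, lapply(seq_along(ms$frames), function(i) {
    idx <- which(ms$masks[[i]], arr.ind = TRUE)
    if (nrow(idx) == 0L) return(NULL)
    data.frame(frame = ms$frames[i], row = idx[, 1], col = idx[, 2])
  }))
  if (is.null(px)) px <- data.frame(frame = integer(), row = integer(),
                                    col = integer())
  utils::write.csv(px, path, row.names = FALSE)
  side <- sub("\\.[^.]+$", ".json", path)
  jsonlite::write_json(list(nrow = nrow(ms$masks[[1]]),
                            ncol = ncol(ms$masks[[1]]),
                            frames = ms$frames,
                            pixel_size_um = ms$pixel_size,
                            origin_um = ms$origin),
                       side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_masks
#' @export
read_masks <- function(path) {
  side <- sub("\\.[^.]+$", ".json", path)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  px <- utils::read.csv(path)
  masks <- lapply(meta$frames, function(f) {
    m <- matrix(FALSE, meta$nrow, meta$ncol)
    sel <- px[px$frame == f, , drop = FALSE]
    if (nrow(sel)) m[cbind(sel$row, sel$col)] <- TRUE
    m
  })
  mask_series(meta$frames, masks, meta$pixel_size_um, meta$origin_um)
}

# ---- kinematics ------------------------------------------------------------

#' Smoothed per-frame speed
#'
#' Instantaneous speed per step is centroid displacement over true elapsed
#' time; the per-frame smoothed value averages the instantaneous speed over
#' the two frames before and the two after the frame in question (the window
#' truncates at track ends).
#'
#' @param track An `sk_track` with at least 2 frames.
#' @return Numeric vector, um/min, one value per frame.
#' @export
smoothed_speed <- function(track) {
  n <- n_frames(track)
  if (n < 2L) stop("no displacement defined for a single-point track")
  dp <- diff(track$positions)
  dt <- diff(track$times)
  inst <- sqrt(rowSums(dp^2)) / dt * 60  # um/min per step i -> i+1
  # step j spans frames (j, j+1); frame i averages steps i-2 .. i+1
  vapply(seq_len(n), function(i) {
    j <- max(1L, i - 2L):min(n - 1L, i + 1L)
    mean(inst[j])
  }, numeric(1))
}

# internal: squared displacement matrix utilities
max_pairwise_distance <- function(xy) {
  if (nrow(xy) < 2L) return(0)
  max(stats::dist(xy))
}
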