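#' Construct a track set
#'
#' A `track_set` is the central trajectory container: a collection of
#' time-ordered cell tracks recorded around a bead, in physical units
#' (seconds and micrometres). Tracks with fewer than two points are dropped
#' with a warning, since a single detection carries no kinematic information.
#'
#' @param tracks Named list of per-track data frames, each with numeric
#'   columns `t` (s), `x` (um), `y` (um). Names are the track ids.
#' @param frame_interval Nominal sampling interval in seconds (> 0).
#' @param duration Recording duration in seconds. Defaults to the latest time
#'   observed in any track.
#'
#' @return An object of class `track_set`: a list with elements `tracks`
#'   (named list of data frames sorted by time), `frame_interval` and
#'   `duration`.
#' @export
#' @examples
#' ts <- track_set(list(a = data.frame(t = 0:3, x = c(0, 1, 2, 3), y = 0)))
#' n_tracks(ts)
track_set <- function(tracks, frame_interval = 1, duration = NULL) {
  stopifnot(is.list(tracks))
  if (length(tracks) > 0 && is.null(names(tracks))) {
    names(tracks) <- paste0("track_", seq_along(tracks))
  }
  if (anyDuplicated(names(tracks))) {
    stop("track ids must be unique", call. = FALSE)
  }
  if (!is.numeric(frame_interval) || length(frame_interval) != 1 ||
      !is.finite(frame_interval) || frame_interval <= 0) {
    stop("'frame_interval' must be a single positive number", call. = FALSE)
  }
  tracks <- lapply(tracks, function(tr) {
    tr <- as.data.frame(tr)[, c("t", "x", "y")]
    if (!all(vapply(tr, is.numeric, logical(1)))) {
      stop("track columns t, x, y must be numeric", call. = FALSE)
    }
    if (any(!is.finite(as.matrix(tr)))) {
      stop("track coordinates and times must be finite", call. = FALSE)
    }
    if (any(tr$t < 0)) stop("track times must be >= 0", call. = FALSE)
    tr <- tr[order(tr$t), , drop = FALSE]
    if (anyDuplicated(tr$t)) {
      stop("duplicated time within a track", call. = FALSE)
    }
    rownames(tr) <- NULL
    tr
  })
  short <- vapply(tracks, nrow, integer(1)) < 2L
  if (any(short)) {
    warning(sum(short), " track(s) with fewer than 2 points dropped",
            call. = FALSE)
    tracks <- tracks[!short]
  }
  if (is.null(duration)) {
    duration <- if (length(tracks) > 0) {
      max(vapply(tracks, function(tr) max(tr$t), numeric(1)))
    } else 0
  }
  structure(
    list(tracks = tracks, frame_interval = frame_interval,
         duration = duration),
    class = "track_set"
  )
}

#' @export
print.track_set <- function(x, ...) {
  npts <- vapply(x$tracks, nrow, integer(1))
  cat("track_set:", length(x$tracks), "tracks,",
      sum(npts), "points\n")
  cat("  frame interval:", x$frame_interval, "s; duration:",
      x$duration, "s\n")
  if (length(npts) > 0) {
    cat("  points per track: median", stats::median(npts),
        "range", min(npts), "-", max(npts), "\n")
  }
  invisible(x)
}

#' Number of tracks in a track set
#' @param x A `track_set`.
#' @return Integer count of tracks.
#' @export
n_tracks <- function(x) {
  stopifnot(inherits(x, "track_set"))
  length(x$tracks)
}

#' Flatten a track set to a long data frame
#'
#' @param x A `track_set`.
#' @param row.names,optional Ignored; present for the generic.
#' @param ... Ignored.
#' @return Data frame with columns `track_id`, `t`, `x`, `y`, points ordered
#'   by time within track.
#' @export
as.data.frame.track_set <- function(x, row.names = NULL, optional = FALSE,
                                    ...) {
  if (length(x$tracks) == 0) {
    return(data.frame(track_id = character(), t = numeric(),
                      x = numeric(), y = numeric()))
  }
  out <- do.call(rbind, Map(function(id, tr) {
    data.frame(track_id = id, tr, stringsAsFactors = FALSE)
  }, names(x$tracks), x$tracks))
  rownames(out) <- NULL
  out
}

#' Define bead-centred assay geometry
#'
#' Describes the concentric-ring binning of the observation field around an
#' alox bead: `n_bins` annuli of width `bin_width` centred on the bead. The
#' default layout is three 112-um bins (bins A-C) spanning a 336-um
#' observation radius.
#'
#' @param bead_x,bead_y Bead centre in um.
#' @param bead_radius Bead radius R in um (>= 0); enters the encounter kernel
#'   beta = 4*pi*R*D and is the reflection radius in the simulator.
#' @param bin_width Radial width of each bin in um (> 0).
#' @param n_bins Number of concentric bins (>= 1).
#'
#' @return An object of class `bead_geometry`.
#' @export
#' @examples
#' geom <- bead_geometry(bead_radius = 50)
#' observation_radius(geom)   # 336 um
#' observation_area_mm2(geom) # ~0.355 mm^2
bead_geometry <- function(bead_x = 0, bead_y = 0, bead_radius = 0,
                          bin_width = 112, n_bins = 3) {
  stopifnot(
    is.numeric(bead_x), is.finite(bead_x),
    is.numeric(bead_y), is.finite(bead_y),
    is.numeric(bead_radius), bead_radius >= 0,
    is.numeric(bin_width), bin_width > 0,
    n_bins >= 1, n_bins == as.integer(n_bins)
  )
  structure(
    list(bead_x = bead_x, bead_y = bead_y, bead_radius = bead_radius,
         bin_width = bin_width, n_bins = as.integer(n_bins)),
    class = "bead_geometry"
  )
}

#' @export
print.bead_geometry <- function(x, ...) {
  cat("bead_geometry: bead at (", x$bead_x, ",", x$bead_y, ") um, R =",
      x$bead_radius, "um\n")
  cat("  ", x$n_bins, "bins of width", x$bin_width,
      "um; observation radius", observation_radius(x), "um\n")
  invisible(x)
}

#' Observation radius of a bead geometry
#' @param geometry A `bead_geometry`.
#' @return `n_bins * bin_width`, in um.
#' @export
observation_radius <- function(geometry) {
  stopifnot(inherits(geometry, "bead_geometry"))
  geometry$n_bins * geometry$bin_width
}

#' Observation (counting) area in mm^2
#'
#' Area of the full observation disc, pi * (n_bins * bin_width)^2, converted
#' from um^2 to mm^2. Three 112-um bins give ~0.355 mm^2.
#'
#' @param geometry A `bead_geometry`.
#' @return Area in mm^2.
#' @export
observation_area_mm2 <- function(geometry) {
  r_um <- observation_radius(geometry)
  pi * r_um^2 / 1e6
}

#' Bin labels (A, B, C, ...) for a geometry
#' @param geometry A `bead_geometry`.
#' @return Character vector of length `n_bins`.
#' @export
bin_labels <- function(geometry) {
  stopifnot(inherits(geometry, "bead_geometry"))
  make.unique(LETTERS[(seq_len(geometry$n_bins) - 1L) %% 26L + 1L])
}

#' Assign positions to concentric bins
#'
#' Maps positions to the concentric annulus they fall in, by distance rho to
#' the bead centre. Bin k (1-based) covers (k-1)*bin_width <= rho <
#' k*bin_width: half-open, lower-inclusive. Positions on the bead itself
#' (rho < bead_radius) count as bin 1 — cells physically contact the bead.
#' Positions at or beyond the observation radius return `NA`.
#'
#' @param x,y Numeric vectors of positions in um (recycled to equal length).
#' @param geometry A `bead_geometry`.
#' @return Integer vector of 1-based bin indices, `NA` for positions outside
#'   the observation disc.
#' @export
#' @examples
#' g <- bead_geometry()
#' radial_bin(c(50, 112, 336), c(0, 0, 0), g)  # 1, 2, NA
radial_bin <- function(x, y, geometry) {
  stopifnot(inherits(geometry, "bead_geometry"))
  rho <- sqrt((x - geometry$bead_x)^2 + (y - geometry$bead_y)^2)
  k <- floor(rho / geometry$bin_width) + 1L
  k[rho < geometry$bead_radius] <- 1L
  k[k > geometry$n_bins] <- NA_integer_
  as.integer(k)
}

#' Distance of positions to the bead centre
#' @param x,y Positions in um.
#' @param geometry A `bead_geometry`.
#' @return Numeric vector of distances in um.
#' @export
bead_distance <- function(x, y, geometry) {
  stopifnot(inherits(geometry, "bead_geometry"))
  sqrt((x - geometry$bead_x)^2 + (y - geometry$bead_y)^2)
}

#' Per-step speeds of one track
#'
#' Instantaneous speeds between consecutive detections:
#' `||p[i+1] - p[i]|| / (t[i+1] - t[i])`, reported at the step's temporal
#' midpoint together with the step's spatial midpoint (used for bin
#' attribution of step statistics).
#'
#' @param track Data frame with columns `t`, `x`, `y` (>= 2 rows, t strictly
#'   increasing), as stored in a `track_set`.
#' @return Data frame with one row per step: `t_mid`, `speed` (um/s),
#'   `x_mid`, `y_mid`, `dt`.
#' @export
#' @examples
#' step_speeds(data.frame(t = 0:1, x = c(0, 3), y = c(0, 4)))$speed  # 5
step_speeds <- function(track) {
  tr <- as.data.frame(track)
  stopifnot(nrow(tr) >= 2, all(c("t", "x", "y") %in% names(tr)))
  dt <- diff(tr$t)
  if (any(dt <= 0)) stop("track times must be strictly increasing",
                         call. = FALSE)
  dx <- diff(tr$x)
  dy <- diff(tr$y)
  data.frame(
    t_mid = tr$t[-nrow(tr)] + dt / 2,
    speed = sqrt(dx^2 + dy^2) / dt,
    x_mid = tr$x[-nrow(tr)] + dx / 2,
    y_mid = tr$y[-nrow(tr)] + dy / 2,
    dt = dt
  )
}
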