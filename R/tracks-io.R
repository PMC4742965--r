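#' Read tracks from a tabular export
#'
#' Reads trajectories from a CSV file with header columns `track_id`,
#' `frame`, `time_s`, `x_um`, `y_um` — the common flat export of cell
#' tracking tools. Points are re-sorted by time within each track;
#' single-point tracks are dropped with a warning.
#'
#' @param path Path to the CSV file.
#' @param frame_interval Sampling interval in seconds recorded in the
#'   resulting `track_set` (default 1).
#' @param calibration_um_per_px Optional calibration factor; when supplied,
#'   the coordinate columns are interpreted as pixels and multiplied by this
#'   factor. Physical-unit exports leave it `NULL`.
#' @return A [track_set].
#' @export
read_tracks_table <- function(path, frame_interval = 1,
                              calibration_um_per_px = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("track_id", "frame", "time_s", "x_um", "y_um")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("track table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  dup <- duplicated(df[, c("track_id", "time_s")])
  if (any(dup)) {
    off <- df[which(dup)[1], ]
    stop("duplicated (track_id, time) pair: track '", off$track_id,
         "' at t = ", off$time_s, " s", call. = FALSE)
  }
  if (!is.null(calibration_um_per_px)) {
    stopifnot(is.numeric(calibration_um_per_px), calibration_um_per_px > 0)
    df$x_um <- df$x_um * calibration_um_per_px
    df$y_um <- df$y_um * calibration_um_per_px
  }
  tracks <- split(df, factor(df$track_id, levels = unique(df$track_id)))
  tracks <- lapply(tracks, function(d) {
    data.frame(t = d$time_s, x = d$x_um, y = d$y_um)
  })
  track_set(tracks, frame_interval = frame_interval)
}

#' Write tracks to a tabular export
#'
#' Inverse of [read_tracks_table]: writes the `track_id, frame, time_s,
#' x_um, y_um` CSV. Frames are reconstructed as `round(t / frame_interval)`.
#'
#' @param x A [track_set].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tracks_table <- function(x, path) {
  stopifnot(inherits(x, "track_set"))
  df <- as.data.frame(x)
  out <- data.frame(
    track_id = df$track_id,
    frame = as.integer(round(df$t / x$frame_interval)),
    time_s = df$t,
    x_um = df$x,
    y_um = df$y
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read tracks from a TrackMate-style XML export
#'
#' Consumes the subset of the TrackMate XML dialect needed for trajectory
#' analysis: `Spot` elements carrying `ID`, `POSITION_X`, `POSITION_Y` and
#' `POSITION_T` (or `FRAME`) attributes, and `Track`/`Edge` elements that
#' group spots into tracks. Everything else (features, filters, settings)
#' is ignored. Spots not referenced by any track edge are dropped.
#'
#' @param path Path to the XML file.
#' @param frame_interval Seconds per frame, used to convert `FRAME` indices
#'   to times when `POSITION_T` is absent (default 1).
#' @return A [track_set].
#' @export
read_tracking_xml <- function(path, frame_interval = 1) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  doc <- xml2::read_xml(path)
  spots <- xml2::xml_find_all(doc, ".//Spot")
  if (length(spots) == 0) stop("no Spot elements found", call. = FALSE)
  spot_attr <- function(attr) xml2::xml_attr(spots, attr)
  ids <- spot_attr("ID")
  px <- spot_attr("POSITION_X")
  py <- spot_attr("POSITION_Y")
  if (anyNA(ids) || anyNA(px) || anyNA(py)) {
    stop("Spot element lacking an ID or coordinate attribute",
         call. = FALSE)
  }
  pt <- spot_attr("POSITION_T")
  if (anyNA(pt)) {
    fr <- spot_attr("FRAME")
    if (anyNA(fr)) {
      stop("Spot element lacking both POSITION_T and FRAME", call. = FALSE)
    }
    pt <- as.numeric(fr) * frame_interval
  } else {
    pt <- as.numeric(pt)
  }
  spot_tab <- data.frame(
    id = ids, t = pt, x = as.numeric(px), y = as.numeric(py),
    stringsAsFactors = FALSE
  )
  track_nodes <- xml2::xml_find_all(doc, ".//Track")
  if (length(track_nodes) == 0) {
    stop("no Track elements found (is this a tracking export?)",
         call. = FALSE)
  }
  tracks <- lapply(track_nodes, function(tn) {
    edges <- xml2::xml_find_all(tn, ".//Edge")
    members <- unique(c(xml2::xml_attr(edges, "SPOT_SOURCE_ID"),
                        xml2::xml_attr(edges, "SPOT_TARGET_ID")))
    members <- members[!is.na(members)]
    d <- spot_tab[spot_tab$id %in% members, , drop = FALSE]
    data.frame(t = d$t, x = d$x, y = d$y)
  })
  names(tracks) <- vapply(track_nodes, function(tn) {
    id <- xml2::xml_attr(tn, "TRACK_ID")
    if (is.na(id)) xml2::xml_attr(tn, "name") else id
  }, character(1))
  track_set(tracks, frame_interval = frame_interval)
}

#' Read assay geometry and run settings from a config file
#'
#' Reads a YAML or JSON key-value file describing the bead assay:
#' `bead_x_um`, `bead_y_um`, `bead_radius_um`, `bin_width_um` (default 112),
#' `n_bins` (default 3), `frame_interval_s` (default 1).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return List with elements `geometry` (a [bead_geometry]) and
#'   `frame_interval` (s).
#' @export
read_geometry_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- c("bead_x_um", "bead_y_um", "bead_radius_um", "bin_width_um",
             "n_bins", "frame_interval_s")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  pick <- function(key, default) if (!is.null(cfg[[key]])) cfg[[key]] else default
  list(
    geometry = bead_geometry(
      bead_x = pick("bead_x_um", 0),
      bead_y = pick("bead_y_um", 0),
      bead_radius = pick("bead_radius_um", 0),
      bin_width = pick("bin_width_um", 112),
      n_bins = pick("n_bins", 3)
    ),
    frame_interval = pick("frame_interval_s", 1)
  )
}
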