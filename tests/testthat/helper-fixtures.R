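# Small in-code fixtures shared across test files.

# one track gliding radially inward along +x toward a bead at the origin
straight_track <- function(t = 0:10, speed = 2, start_x = 100) {
  data.frame(t = t, x = start_x - speed * t, y = 0)
}

# track set of cells parked at given radii (static), sampled at 1 fps
static_radial_set <- function(radii, duration = 600) {
  tracks <- lapply(seq_along(radii), function(i) {
    data.frame(t = seq(0, duration), x = radii[i], y = 0)
  })
  names(tracks) <- paste0("cell", seq_along(radii))
  track_set(tracks, frame_interval = 1, duration = duration)
}

default_geom <- function(bead_radius = 50) bead_geometry(bead_radius = bead_radius)

write_tracks_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# minimal TrackMate-flavoured XML with two tracks' worth of structure
trackmate_xml <- function(path = tempfile(fileext = ".xml"),
                          orphan_spot = FALSE, drop_coord = FALSE,
                          drop_tracks = FALSE, use_frame = FALSE) {
  tpos <- function(i) {
    if (use_frame) sprintf('FRAME="%d"', i) else
      sprintf('POSITION_T="%d"', i)
  }
  spot <- function(id, i, x, y, coord = TRUE) {
    if (coord) {
      sprintf('<Spot ID="%d" %s POSITION_X="%g" POSITION_Y="%g"/>',
              id, tpos(i), x, y)
    } else {
      sprintf('<Spot ID="%d" %s POSITION_Y="%g"/>', id, tpos(i), y)
    }
  }
  spots <- c(
    spot(1, 0, 10, 0, coord = !drop_coord),
    spot(2, 1, 12, 0),
    if (orphan_spot) spot(99, 0, 500, 500)
  )
  tracks <- if (drop_tracks) "" else paste0(
    '<Model><AllTracks><Track TRACK_ID="0" name="trk0">',
    '<Edge SPOT_SOURCE_ID="1" SPOT_TARGET_ID="2"/>',
    "</Track></AllTracks></Model>"
  )
  xml <- paste0(
    '<?xml version="1.0"?><TrackMate><AllSpots>',
    paste(spots, collapse = ""),
    "</AllSpots>", tracks, "</TrackMate>"
  )
  writeLines(xml, path)
  path
}
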