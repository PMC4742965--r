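test_that("tabular reader builds tracks, re-sorts times, drops singletons", {
  path <- write_tracks_csv(data.frame(
    track_id = c("trk1", "trk1"), frame = 0:1, time_s = 0:1,
    x_um = c(0, 3), y_um = c(0, 4)
  ))
  ts <- read_tracks_table(path)
  expect_equal(n_tracks(ts), 1)
  expect_equal(nrow(ts$tracks$trk1), 2)

  # out-of-order times are accepted and re-sorted
  path2 <- write_tracks_csv(data.frame(
    track_id = "a", frame = c(5, 3), time_s = c(5, 3),
    x_um = c(10, 6), y_um = 0
  ))
  ts2 <- read_tracks_table(path2)
  expect_equal(ts2$tracks$a$t, c(3, 5))
  expect_equal(ts2$tracks$a$x, c(6, 10))

  # a lone detection is dropped with a warning, not an error
  path3 <- write_tracks_csv(data.frame(
    track_id = "solo", frame = 0, time_s = 0, x_um = 1, y_um = 1
  ))
  expect_warning(ts3 <- read_tracks_table(path3), "fewer than 2")
  expect_equal(n_tracks(ts3), 0)
})

test_that("tabular reader rejects malformed files informatively", {
  path <- write_tracks_csv(data.frame(
    track_id = "a", frame = 0:1, time_s = 0:1, x_um = 0:1
  ))
  expect_error(read_tracks_table(path), "y_um")

  path2 <- write_tracks_csv(data.frame(
    track_id = "dup", frame = c(0, 0), time_s = c(0, 0),
    x_um = c(0, 1), y_um = 0
  ))
  expect_error(read_tracks_table(path2), "dup")
  expect_error(read_tracks_table(tempfile()), "not found")
})

test_that("write/read round trip preserves ids, times and coordinates", {
  ts <- track_set(list(
    a = data.frame(t = 0:5, x = sin(0:5), y = cos(0:5)),
    b = data.frame(t = seq(0, 10, 2), x = 0:5 * 1.5, y = -(0:5))
  ))
  path <- tempfile(fileext = ".csv")
  write_tracks_table(ts, path)
  back <- read_tracks_table(path)
  expect_equal(names(back$tracks), names(ts$tracks))
  for (id in names(ts$tracks)) {
    expect_equal(back$tracks[[id]], ts$tracks[[id]], tolerance = 1e-12)
  }
})

test_that("XML reader consumes spots, track membership and frame times", {
  ts <- read_tracking_xml(trackmate_xml())
  expect_equal(n_tracks(ts), 1)
  expect_equal(nrow(ts$tracks[[1]]), 2)
  expect_equal(ts$tracks[[1]]$x, c(10, 12))

  # spots outside any track are ignored
  ts2 <- read_tracking_xml(trackmate_xml(orphan_spot = TRUE))
  expect_equal(n_tracks(ts2), 1)
  expect_false(any(vapply(ts2$tracks, function(tr) any(tr$x == 500),
                          logical(1))))

  # FRAME-indexed spots get times frame * frame_interval
  ts3 <- read_tracking_xml(trackmate_xml(use_frame = TRUE),
                           frame_interval = 2)
  expect_equal(ts3$tracks[[1]]$t, c(0, 2))
})

test_that("XML reader rejects structurally deficient exports", {
  expect_error(read_tracking_xml(trackmate_xml(drop_coord = TRUE)),
               "coordinate")
  expect_error(read_tracking_xml(trackmate_xml(drop_tracks = TRUE)),
               "Track")
})

test_that("geometry config reader applies defaults and rejects unknown keys", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c("bead_x_um: 10", "bead_radius_um: 40"), path)
  cfg <- read_geometry_config(path)
  expect_equal(cfg$geometry$bead_x, 10)
  expect_equal(cfg$geometry$bin_width, 112)
  expect_equal(cfg$geometry$n_bins, 3)
  expect_equal(cfg$frame_interval, 1)

  bad <- tempfile(fileext = ".yaml")
  writeLines("bead_diameter: 5", bad)
  expect_error(read_geometry_config(bad), "bead_diameter")
})

test_that("radial binning follows the half-open lower-inclusive convention", {
  g <- default_geom(bead_radius = 20)
  expect_equal(radial_bin(50, 0, g), 1L)   # bin A
  expect_equal(radial_bin(112, 0, g), 2L)  # boundary goes to the outer bin
  expect_equal(radial_bin(224, 0, g), 3L)
  expect_true(is.na(radial_bin(336, 0, g)))  # excluded upper edge
  expect_equal(radial_bin(5, 0, g), 1L)      # on the bead counts as bin A
})

test_that("radial binning partitions the observation disc", {
  g <- bead_geometry(bead_x = 7, bead_y = -3, bead_radius = 10,
                     bin_width = 35, n_bins = 4)
  set.seed(42)
  rho <- runif(500, 0, 4 * 35 - 1e-9)
  ang <- runif(500, 0, 2 * pi)
  bins <- radial_bin(7 + rho * cos(ang), -3 + rho * sin(ang), g)
  expect_false(anyNA(bins))
  expect_true(all(bins >= 1 & bins <= 4))
  # and agrees with direct interval arithmetic off the bead
  off <- rho >= 10
  expect_equal(bins[off], as.integer(floor(rho[off] / 35) + 1))
})

test_that("step speeds reproduce elementary kinematics", {
  expect_equal(step_speeds(data.frame(t = 0:1, x = c(0, 3),
                                      y = c(0, 4)))$speed, 5)
  expect_equal(step_speeds(data.frame(t = c(0, 2), x = c(0, 2),
                                      y = 0))$speed, 1)
  expect_equal(step_speeds(data.frame(t = 0:1, x = 1, y = 1))$speed, 0)
  tr <- straight_track()
  expect_length(step_speeds(tr)$speed, nrow(tr) - 1)
})

test_that("step speeds are invariant under rigid motions", {
  set.seed(7)
  tr <- data.frame(t = 0:20, x = cumsum(rnorm(21)), y = cumsum(rnorm(21)))
  phi <- 0.83
  rot <- data.frame(
    t = tr$t,
    x = cos(phi) * tr$x - sin(phi) * tr$y + 50,
    y = sin(phi) * tr$x + cos(phi) * tr$y - 12
  )
  expect_equal(step_speeds(rot)$speed, step_speeds(tr)$speed,
               tolerance = 1e-12)
})

test_that("track_set enforces its invariants", {
  expect_error(track_set(list(a = data.frame(t = 1, x = 1, y = 1),
                              a = data.frame(t = 0:1, x = 0:1, y = 0))),
               "unique")
  expect_error(track_set(list(), frame_interval = 0), "positive")
  expect_error(
    track_set(list(a = data.frame(t = c(0, 0), x = 0:1, y = 0))),
    "duplicated"
  )
  expect_error(
    track_set(list(a = data.frame(t = c(0, Inf), x = 0:1, y = 0))),
    "finite"
  )
})
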