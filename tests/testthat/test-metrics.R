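test_that("frame bin counts follow the binning and sampling grid", {
  geom <- default_geom(bead_radius = 20)
  ts <- static_radial_set(c(50, 150, 400), duration = 600)
  counts <- frame_bin_counts(ts, geom, interval_s = 60)
  at0 <- counts[counts$time_s == 0, ]
  expect_equal(at0$value[at0$bin == "A"], 1)
  expect_equal(at0$value[at0$bin == "B"], 1)
  expect_equal(at0$value[at0$bin == "C"], 0)  # 400 um is outside
  # 600 s at 60-s interval: 11 sampled time points, 0-600 inclusive
  expect_equal(sort(unique(counts$time_s)), seq(0, 600, 60))

  # exactly on a bin boundary counts toward the outer bin
  edge <- static_radial_set(224, duration = 60)
  c2 <- frame_bin_counts(edge, geom, interval_s = 60)
  expect_equal(c2$value[c2$bin == "C" & c2$time_s == 0], 1)
  expect_error(frame_bin_counts(ts, geom, interval_s = 0.5), "multiple")
})

test_that("bin counts never exceed the number of tracks alive", {
  cfg <- simulation_config(n_cells = 30, duration = 120, seed = 13)
  sim <- simulate_tracks(cfg, scenario_params("control"))
  geom <- default_geom()
  counts <- frame_bin_counts(sim, geom, interval_s = 30)
  per_time <- tapply(counts$value, counts$time_s, sum)
  expect_true(all(per_time <= n_tracks(sim)))
})

test_that("count normalization matches the Z-score hand calculation", {
  x <- data.frame(bin = "A", time_s = c(0, 60, 120), value = c(2, 4, 6))
  out <- normalize_counts(x)
  # population sd of (2,4,6) is 1.633; Z = (-1.2247, 0, 1.2247);
  # anchoring t = 0 at zero shifts to (0, 1.2247, 2.4495)
  expect_equal(out$value, c(0, 1.224745, 2.449490), tolerance = 1e-6)

  expect_warning(
    flat <- normalize_counts(data.frame(bin = "A", time_s = c(0, 60),
                                        value = c(3, 3))),
    "zero variance")
  expect_equal(flat$value, c(0, 0))
  expect_error(
    normalize_counts(data.frame(bin = "A", time_s = c(60, 120),
                                value = 1:2)),
    "baseline")
})

test_that("normalization anchors every series at zero and ignores scale", {
  set.seed(3)
  df <- expand.grid(bin = c("A", "B"), replicate = 1:2,
                    time_s = seq(0, 300, 60))
  df$value <- rpois(nrow(df), 20)
  out <- normalize_counts(df)
  base <- out[out$time_s == 0, ]
  expect_true(all(base$value == 0))
  # invariance under affine rescaling of the raw counts per population
  df2 <- df
  df2$value <- 5 * df2$value + 7
  expect_equal(normalize_counts(df2)$value, out$value, tolerance = 1e-12)
})

test_that("sine angle realizes the stated sign convention and bounds", {
  bead <- c(0, 0)
  expect_equal(step_sine_angle(c(100, 0), c(90, 0), bead), 1)
  expect_equal(step_sine_angle(c(100, 0), c(110, 0), bead), -1)
  expect_equal(step_sine_angle(c(100, 0), c(100, 10), bead), -0.0498756,
               tolerance = 1e-6)
  expect_true(is.na(step_sine_angle(c(5, 5), c(5, 5), bead)))

  # bounded in [-1, 1]; antisymmetric under reversing the step
  set.seed(8)
  pf <- matrix(runif(200, -300, 300), ncol = 2)
  pt <- pf + matrix(rnorm(200, sd = 4), ncol = 2)
  s <- step_sine_angle(pf, pt, bead)
  expect_true(all(abs(s) <= 1 + 1e-12, na.rm = TRUE))
  expect_equal(step_sine_angle(pt, pf, bead), -s, tolerance = 1e-12)
})

test_that("binned mean sine averages steps and excludes lone tracks", {
  geom <- default_geom(bead_radius = 20)
  inward <- track_set(list(
    a = straight_track(t = 0:60, speed = 1, start_x = 100),
    b = data.frame(t = 0:60, x = 0, y = 90 - (0:60) * 0.5)
  ))
  out <- binned_mean_sine(inward, geom, interval_s = 60)
  expect_equal(out$value[out$bin == "A" & out$time_s == 0], 1,
               tolerance = 1e-9)
  # with a single contributing track the window is missing
  lone <- track_set(list(a = straight_track(t = 0:60, speed = 1,
                                            start_x = 100)))
  out2 <- binned_mean_sine(lone, geom, interval_s = 60)
  expect_true(all(is.na(out2$value)))
  expect_equal(out2$n[out2$bin == "A"], 1L)
})

test_that("sum distance sums per-bin bead distances", {
  geom <- default_geom(bead_radius = 20)
  ts <- static_radial_set(c(50, 70, 150), duration = 120)
  out <- sum_distance_series(ts, geom, interval_s = 60)
  a_rows <- out[out$bin == "A", ]
  expect_true(all(a_rows$value == 120))   # 50 + 70
  expect_true(all(out$value[out$bin == "B"] == 150))
  expect_true(all(out$value[out$bin == "total"] == 270))
  # static cells give an exactly constant series
  expect_equal(length(unique(out$value[out$bin == "total"])), 1)
})

test_that("trend slope matches exact lines and guards short input", {
  tt <- 0:10
  # exact lines make summary.lm warn about perfect fits; that is the point
  suppressWarnings({
  exact <- trend_slope(data.frame(time_s = tt, value = 100 - 2 * tt))
  expect_equal(exact$slope, -2)
  expect_equal(exact$se, 0)
  expect_equal(trend_slope(data.frame(time_s = tt,
                                      value = rep(5, 11)))$slope, 0)
  tri <- trend_slope(data.frame(time_s = 0:2, value = 0:2))
  })
  expect_equal(tri$slope, 1)
  expect_equal(tri$se, 0)
  expect_error(trend_slope(data.frame(time_s = 0:1, value = 0:1)),
               "3")
  # missing values are dropped before counting
  expect_error(trend_slope(data.frame(time_s = 0:3,
                                      value = c(1, NA, NA, 2))), "3")
})
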