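test_that("RMS net displacement reproduces hand-computable cases", {
  # ballistic identity: a straight-line track at 2 um/s has rms(t) = 2t
  ts <- track_set(list(a = straight_track(t = 0:300, speed = 2,
                                          start_x = 700)))
  rms <- rms_net_displacement(ts, time_grid = c(10, 50, 100, 250))
  expect_equal(rms$rms_um, 2 * c(10, 50, 100, 250), tolerance = 1e-12)

  # definition: net distances 3 and 4 at t = 10 pool to sqrt(25/2)
  two <- track_set(list(
    p = data.frame(t = c(0, 10), x = c(0, 3), y = 0),
    q = data.frame(t = c(0, 10), x = 0, y = c(0, 4))
  ))
  out <- rms_net_displacement(two, time_grid = 10)
  expect_equal(out$rms_um, sqrt((9 + 16) / 2), tolerance = 1e-12)
  expect_equal(out$n_tracks, 2L)
})

test_that("short tracks are excluded beyond their span", {
  ts <- track_set(list(
    long = straight_track(t = 0:500, speed = 1, start_x = 600),
    short = straight_track(t = 0:300, speed = 1, start_x = 400)
  ))
  out <- rms_net_displacement(ts, time_grid = c(200, 400))
  expect_equal(out$n_tracks, c(2L, 1L))
  expect_error(rms_net_displacement(track_set(list())), "empty")
})

test_that("RMS series is invariant under rigid motions of all tracks", {
  set.seed(11)
  mk <- function(shift, phi) {
    lapply(1:5, function(i) {
      x <- cumsum(rnorm(61)); y <- cumsum(rnorm(61))
      data.frame(t = 0:60,
                 x = cos(phi) * x - sin(phi) * y + shift[1],
                 y = sin(phi) * x + cos(phi) * y + shift[2])
    })
  }
  set.seed(123); a <- track_set(mk(c(0, 0), 0))
  set.seed(123); b <- track_set(mk(c(100, -40), 1.1))
  expect_equal(rms_net_displacement(b, time_grid = c(5, 20, 60))$rms_um,
               rms_net_displacement(a, time_grid = c(5, 20, 60))$rms_um,
               tolerance = 1e-10)
})

test_that("Taylor fit recovers noiseless model parameters exactly", {
  s <- data.frame(time_s = 1:600, rms_um = taylor_rms(1:600, v = 2,
                                                      tau = 10))
  fit <- fit_taylor(s)
  expect_lt(abs(fit$v - 2) / 2, 1e-4)
  expect_lt(abs(fit$tau - 10) / 10, 1e-4)
  expect_true(fit$converged)
  expect_false(fit$non_identifiable)
})

test_that("a purely ballistic series is flagged non-identifiable", {
  s <- data.frame(time_s = 1:100, rms_um = 1.5 * (1:100))
  fit <- fit_taylor(s)
  expect_true(fit$non_identifiable)
  expect_gt(fit$tau, 100)  # tau driven past the observation span
})

test_that("Taylor fit input contract is enforced", {
  expect_error(fit_taylor(data.frame(time_s = 1:3, rms_um = 1:3)),
               "5")
  expect_error(
    fit_taylor(data.frame(time_s = 1:6, rms_um = rep(0, 6))),
    "positive")
})

test_that("Taylor model has the correct ballistic and diffusive limits", {
  v <- 1.7; tau <- 12
  # t << tau: rms -> v t
  t_small <- tau * c(1e-4, 1e-3)
  expect_equal(taylor_rms(t_small, v, tau), v * t_small,
               tolerance = 1e-3)
  # t >> tau: rms^2 -> 4 D t with D = v^2 tau / 2 (two dimensions)
  D <- v^2 * tau / 2
  t_big <- tau * 1e5
  expect_equal(taylor_rms(t_big, v, tau)^2 / (4 * D * t_big), 1,
               tolerance = 1e-4)
})

test_that("derived motility parameters satisfy their defining identities", {
  fit <- taylor_fit(v = 1.6067, tau = 14.85)
  fit <- derive_motility_params(fit, bead_radius = 50)
  expect_equal(fit$lambda, 1.6067 * 14.85)          # lambda = v tau
  expect_equal(fit$lambda, 23.86, tolerance = 1e-3)
  expect_equal(fit$D, 1.6067^2 * 14.85 / 2)         # D = v^2 tau / n
  expect_equal(fit$beta, 4 * pi * 50 * fit$D)       # beta = 4 pi R D
  expect_equal(4 * pi * 50 * 19.17, 1.204e4, tolerance = 1e-3)
  expect_error(derive_motility_params(fit, bead_radius = -1), ">= 0")
})

test_that("printed decorrelation parameters reproduce published D values", {
  # D = lambda^2 / (n tau) with n = 2 spatial dimensions
  dsi <- derive_motility_params(taylor_fit(tau = 14.85, lambda = 23.86))
  ctrl <- derive_motility_params(taylor_fit(tau = 4.68, lambda = 10.70))
  expect_equal(dsi$D, 19.17, tolerance = 2e-4)
  expect_equal(ctrl$D, 12.22, tolerance = 1e-3)
  # n = 3 would give a decisively different control value (~8.15)
  ctrl3 <- derive_motility_params(taylor_fit(tau = 4.68, lambda = 10.70),
                                  n_dims = 3)
  expect_equal(ctrl3$D, 8.15, tolerance = 1e-3)
})

test_that("condition comparison returns percent differences and guards", {
  a <- derive_motility_params(taylor_fit(v = 2, tau = 5),
                              bead_radius = 50)
  cmp_same <- compare_motility(a, a)
  expect_true(all(cmp_same$percent_change == 0))

  b <- derive_motility_params(taylor_fit(v = 2, tau = 10),
                              bead_radius = 50)
  cmp <- compare_motility(a, b)
  expect_equal(cmp$percent_change[cmp$parameter == "tau"], 100)
  expect_equal(cmp$percent_change[cmp$parameter == "D"], 100)

  # a missing reference parameter yields a flagged (NA) entry
  no_beta <- derive_motility_params(taylor_fit(v = 2, tau = 5))
  expect_true(is.na(
    compare_motility(no_beta, b)$percent_change[cmp$parameter == "beta"]))
})
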