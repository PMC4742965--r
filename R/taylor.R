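#' Root-mean-square net displacement of a track set
#'
#' For each requested elapsed time `t`, computes each track's net distance
#' from its own starting point, `net_i(t) = ||p_i(t0_i + t) - p_i(t0_i)||`,
#' with positions linearly interpolated between frames, and returns
#' `rms(t) = sqrt(mean(net_i(t)^2))` over the tracks long enough to
#' contribute. Tracks shorter than `t` are excluded at that grid point;
#' grid points with no contributing track are dropped.
#'
#' @param trackset A [track_set] with at least one track.
#' @param time_grid Elapsed times in s (default: every frame interval up to
#'   the longest track).
#' @param method `"origin"` (default) measures displacement from each
#'   track's first point; `"all_lag"` averages the squared displacement over
#'   every frame pair separated by the lag (overlapping windows), a more
#'   statistically efficient but autocorrelated estimator kept for
#'   robustness comparisons.
#' @return An object of class `rms_series`: a data frame with columns
#'   `time_s`, `rms_um`, `n_tracks`.
#' @export
rms_net_displacement <- function(trackset, time_grid = NULL,
                                 method = c("origin", "all_lag")) {
  stopifnot(inherits(trackset, "track_set"))
  method <- match.arg(method)
  if (length(trackset$tracks) == 0) {
    stop("track set is empty", call. = FALSE)
  }
  spans <- vapply(trackset$tracks, function(tr) max(tr$t) - min(tr$t),
                  numeric(1))
  if (is.null(time_grid)) {
    time_grid <- seq(trackset$frame_interval, max(spans),
                     by = trackset$frame_interval)
  }
  stopifnot(all(time_grid > 0), !is.unsorted(time_grid))

  if (method == "origin") {
    sq <- vapply(trackset$tracks, function(tr) {
      ok <- time_grid <= max(tr$t) - min(tr$t)
      out <- rep(NA_real_, length(time_grid))
      if (any(ok)) {
        tt <- min(tr$t) + time_grid[ok]
        xi <- stats::approx(tr$t, tr$x, xout = tt)$y
        yi <- stats::approx(tr$t, tr$y, xout = tt)$y
        out[ok] <- (xi - tr$x[1])^2 + (yi - tr$y[1])^2
      }
      out
    }, numeric(length(time_grid)))
    sq <- matrix(sq, nrow = length(time_grid))
    n_at_t <- rowSums(!is.na(sq))
    msd <- rowMeans(sq, na.rm = TRUE)
  } else {
    # pooled over all frame pairs at each lag, weighted by pair counts
    msd <- numeric(length(time_grid))
    n_at_t <- integer(length(time_grid))
    acc_sum <- numeric(length(time_grid))
    acc_n <- numeric(length(time_grid))
    for (tr in trackset$tracks) {
      for (k in seq_along(time_grid)) {
        lag <- time_grid[k]
        if (lag > max(tr$t) - min(tr$t)) next
        t_from <- tr$t[tr$t + lag <= max(tr$t) + 1e-9]
        xi <- stats::approx(tr$t, tr$x, xout = t_from + lag)$y
        yi <- stats::approx(tr$t, tr$y, xout = t_from + lag)$y
        x0 <- stats::approx(tr$t, tr$x, xout = t_from)$y
        y0 <- stats::approx(tr$t, tr$y, xout = t_from)$y
        d2 <- (xi - x0)^2 + (yi - y0)^2
        acc_sum[k] <- acc_sum[k] + sum(d2)
        acc_n[k] <- acc_n[k] + length(d2)
        n_at_t[k] <- n_at_t[k] + 1L
      }
    }
    msd <- acc_sum / acc_n
  }

  keep <- n_at_t > 0
  structure(
    data.frame(time_s = time_grid[keep], rms_um = sqrt(msd[keep]),
               n_tracks = as.integer(n_at_t[keep])),
    class = c("rms_series", "data.frame")
  )
}

#' Taylor's-equation RMS displacement model
#'
#' The closed form for the root-mean-square net displacement of a randomly
#' reorienting swimmer with effective speed `v` and decorrelation timescale
#' `tau`: `rms(t) = sqrt(2 * v^2 * tau * (t - tau * (1 - exp(-t / tau))))`.
#' Ballistic at short times (`rms -> v t` for `t << tau`) and diffusive at
#' long times (`rms^2 -> 2 v^2 tau t = 4 D t` in two dimensions).
#'
#' @param t Elapsed times in s.
#' @param v Effective speed in um/s.
#' @param tau Decorrelation timescale in s.
#' @return RMS displacement in um.
#' @export
taylor_rms <- function(t, v, tau) {
  sqrt(pmax(0, 2 * v^2 * tau * (t - tau * (1 - exp(-t / tau)))))
}

#' Fit Taylor's equation to an RMS displacement series
#'
#' Nonlinear least squares for `(v, tau)` in the Taylor RMS model, both
#' constrained positive. Fitting uses bounded Levenberg-Marquardt with a
#' deterministic multi-start over `tau` starting values; the best converged
#' candidate is returned. Two standard MSD-fitting precautions are applied
#' by default: the series is thinned to approximately log-spaced lags, so
#' the densely sampled (and strongly autocorrelated) diffusive tail does
#' not swamp the short ballistic regime that identifies `v`; and residuals
#' are weighted relatively (1/rms^2), matching the multiplicative error
#' structure of an RMS estimate. A fit whose `tau` exceeds the observed
#' time span is flagged non-identifiable (the series is indistinguishable
#' from purely ballistic motion over the observation window).
#'
#' @param rms_series An [rms_net_displacement] result, or any data frame
#'   with columns `time_s` and `rms_um` (>= 5 points).
#' @param n_dims Number of spatial dimensions (default 2); stored for the
#'   derived parameters.
#' @param v0 Optional starting value for `v`; defaults to the early-time
#'   slope `rms(t_min) / t_min`.
#' @param tau_starts Deterministic sequence of `tau` starting values in s.
#' @param thin `"log"` (default) fits on ~`n_lags` log-spaced lags;
#'   `"none"` uses every point.
#' @param weighting `"relative"` (default) weights residuals by `1/rms^2`;
#'   `"none"` gives unweighted least squares.
#' @param n_lags Target number of lags kept when `thin = "log"`.
#' @return An object of class `taylor_fit` with elements `v`, `tau`,
#'   `n_dims`, `residual_norm`, `converged`, `non_identifiable`,
#'   `n_tracks`; the derived `lambda`, `D`, `beta`, `bead_radius` are `NA`
#'   until completed by [derive_motility_params].
#' @export
#' @examples
#' s <- data.frame(time_s = 1:600, rms_um = taylor_rms(1:600, 2, 10))
#' fit <- fit_taylor(s)
#' c(fit$v, fit$tau)  # ~ (2, 10)
fit_taylor <- function(rms_series, n_dims = 2, v0 = NULL,
                       tau_starts = c(10, 1, 5, 20, 60),
                       thin = c("log", "none"),
                       weighting = c("relative", "none"),
                       n_lags = 60) {
  thin <- match.arg(thin)
  weighting <- match.arg(weighting)
  s <- as.data.frame(rms_series)
  stopifnot(all(c("time_s", "rms_um") %in% names(s)))
  s <- s[is.finite(s$time_s) & is.finite(s$rms_um) & s$time_s > 0, ]
  if (nrow(s) < 5) stop("need at least 5 positive time points",
                        call. = FALSE)
  if (all(s$rms_um <= 0)) stop("RMS series must be positive beyond t = 0",
                               call. = FALSE)
  if (thin == "log" && nrow(s) > n_lags) {
    idx <- unique(round(exp(seq(log(1), log(nrow(s)), length.out = n_lags))))
    s <- s[idx, , drop = FALSE]
  }
  w <- if (weighting == "relative") 1 / pmax(s$rms_um, 1e-12)^2 else
    rep(1, nrow(s))
  t_max <- max(s$time_s)
  if (is.null(v0)) v0 <- s$rms_um[1] / s$time_s[1]
  v0 <- max(v0, 1e-6)

  best <- NULL
  for (tau0 in tau_starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        rms_um ~ taylor_rms(time_s, v, tau),
        data = s,
        start = list(v = v0, tau = tau0),
        lower = c(v = 1e-8, tau = 1e-8),
        upper = c(v = Inf, tau = 100 * t_max),
        weights = w,
        control = minpack.lm::nls.lm.control(maxiter = 500)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    res <- s$rms_um - taylor_rms(s$time_s, stats::coef(fit)["v"],
                                 stats::coef(fit)["tau"])
    obj <- sum(w * res^2)  # weighted objective selects among starts
    if (is.null(best) || obj < best$objective - 1e-12) {
      cf <- stats::coef(fit)
      best <- list(v = unname(cf["v"]), tau = unname(cf["tau"]),
                   objective = obj,
                   residual_norm = sqrt(sum(res^2)), converged = TRUE)
    }
  }
  if (is.null(best)) {
    stop("Taylor fit failed to converge from any starting value; ",
         "tau starts tried: ", paste(tau_starts, collapse = ", "),
         call. = FALSE)
  }
  n_tr <- if ("n_tracks" %in% names(s)) max(s$n_tracks) else NA_integer_
  structure(
    list(v = best$v, tau = best$tau,
         lambda = NA_real_, D = NA_real_, beta = NA_real_,
         n_dims = n_dims, bead_radius = NA_real_,
         residual_norm = best$residual_norm,
         converged = best$converged,
         non_identifiable = best$tau > t_max,
         n_tracks = n_tr),
    class = "taylor_fit"
  )
}

#' Construct a Taylor fit from known parameters
#'
#' Builds a `taylor_fit` directly from parameter values — for example the
#' published columns of a motility-parameter table — so that derived
#' parameters and condition comparisons can be computed without refitting.
#' Supply `v` or `lambda` (with `tau`); the other is filled via
#' `lambda = v * tau`.
#'
#' @param v Effective speed in um/s (optional if `lambda` given).
#' @param tau Decorrelation timescale in s.
#' @param lambda Decorrelation length in um (optional if `v` given).
#' @param D Effective diffusivity in um^2/s (optional; derived otherwise).
#' @param beta Encounter kernel in um^3/s (optional; derived otherwise).
#' @param n_dims Number of spatial dimensions (default 2).
#' @param n_tracks Number of tracks behind the estimate (optional).
#' @return A `taylor_fit`.
#' @export
#' @examples
#' si <- taylor_fit(tau = 14.85, lambda = 23.86)
#' derive_motility_params(si)$D  # ~19.17 um^2/s
taylor_fit <- function(v = NULL, tau, lambda = NULL, D = NULL, beta = NULL,
                       n_dims = 2, n_tracks = NA_integer_) {
  if (is.null(v) && is.null(lambda)) {
    stop("supply 'v' or 'lambda'", call. = FALSE)
  }
  stopifnot(is.numeric(tau), tau > 0)
  if (is.null(v)) v <- lambda / tau
  if (is.null(lambda)) lambda <- NA_real_
  stopifnot(v > 0)
  structure(
    list(v = v, tau = tau, lambda = lambda,
         D = if (is.null(D)) NA_real_ else D,
         beta = if (is.null(beta)) NA_real_ else beta,
         n_dims = n_dims, bead_radius = NA_real_,
         residual_norm = NA_real_, converged = NA,
         non_identifiable = FALSE,
         n_tracks = n_tracks),
    class = "taylor_fit"
  )
}

#' @export
print.taylor_fit <- function(x, ...) {
  cat("taylor_fit: v =", signif(x$v, 4), "um/s, tau =", signif(x$tau, 4),
      "s\n")
  if (!is.na(x$lambda)) cat("  lambda =", signif(x$lambda, 4), "um\n")
  if (!is.na(x$D)) cat("  D =", signif(x$D, 4), "um^2/s (n =", x$n_dims,
                       "dims)\n")
  if (!is.na(x$beta)) cat("  beta =", signif(x$beta, 4), "um^3/s (R =",
                          x$bead_radius, "um)\n")
  if (isTRUE(x$non_identifiable)) {
    cat("  WARNING: tau exceeds the observed time span;",
        "ballistic, non-identifiable fit\n")
  }
  invisible(x)
}

#' Complete a Taylor fit with derived motility parameters
#'
#' Fills the derived parameters from the fitted `v` and `tau`:
#' decorrelation length `lambda = v * tau` (um), effective diffusivity
#' `D = v^2 * tau / n` (um^2/s, `n` spatial dimensions), and — when a bead
#' radius is supplied — the encounter kernel `beta = 4 * pi * R * D`
#' (um^3/s), the water volume searched per unit time for a target of radius
#' `R`. Values already present (e.g. taken from a published table) are kept.
#'
#' @param fit A `taylor_fit` with positive `v` and `tau`.
#' @param n_dims Number of spatial dimensions (default: the fit's, else 2).
#' @param bead_radius Target (bead) radius R in um (>= 0); required for
#'   `beta`. No default: R must be stated explicitly.
#' @return The completed `taylor_fit`.
#' @export
derive_motility_params <- function(fit, n_dims = NULL, bead_radius = NULL) {
  stopifnot(inherits(fit, "taylor_fit"), fit$v > 0, fit$tau > 0)
  if (!is.null(n_dims)) fit$n_dims <- n_dims
  if (is.na(fit$lambda)) fit$lambda <- fit$v * fit$tau
  if (is.na(fit$D)) fit$D <- fit$v^2 * fit$tau / fit$n_dims
  if (!is.null(bead_radius)) {
    if (!is.numeric(bead_radius) || bead_radius < 0) {
      stop("bead_radius must be >= 0", call. = FALSE)
    }
    fit$bead_radius <- bead_radius
    if (is.na(fit$beta)) fit$beta <- 4 * pi * bead_radius * fit$D
  }
  fit
}

#' Compare motility parameters between two conditions
#'
#' Percent change of each motility parameter from condition `a` to
#' condition `b`: `100 * (b - a) / a`. Undefined entries (parameter missing
#' or zero in `a`) are returned as `NA`.
#'
#' @param fit_a,fit_b Completed `taylor_fit` objects (reference and
#'   comparison conditions).
#' @return Data frame with columns `parameter`, `a`, `b`,
#'   `percent_change`.
#' @export
#' @examples
#' ctrl <- derive_motility_params(taylor_fit(tau = 4.68, lambda = 10.70))
#' dsi <- derive_motility_params(taylor_fit(tau = 14.85, lambda = 23.86))
#' compare_motility(ctrl, dsi)  # D rises by ~57%
compare_motility <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "taylor_fit"), inherits(fit_b, "taylor_fit"))
  pars <- c("v", "tau", "lambda", "D", "beta")
  a <- vapply(pars, function(p) as.numeric(fit_a[[p]]), numeric(1))
  b <- vapply(pars, function(p) as.numeric(fit_b[[p]]), numeric(1))
  pc <- ifelse(!is.na(a) & a != 0 & !is.na(b), 100 * (b - a) / a,
               NA_real_)
  data.frame(parameter = pars, a = a, b = b, percent_change = pc,
             row.names = NULL)
}
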