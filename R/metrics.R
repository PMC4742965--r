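#' Interpolated positions of all tracks at one time point
#'
#' Internal helper: linear interpolation of every track's position at time
#' `t`, restricted to tracks whose span covers `t`.
#' @noRd
positions_at <- function(trackset, t) {
  out <- lapply(names(trackset$tracks), function(id) {
    tr <- trackset$tracks[[id]]
    if (t < min(tr$t) - 1e-9 || t > max(tr$t) + 1e-9) return(NULL)
    data.frame(
      track_id = id,
      x = stats::approx(tr$t, tr$x, xout = t, rule = 2)$y,
      y = stats::approx(tr$t, tr$y, xout = t, rule = 2)$y
    )
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0) {
    return(data.frame(track_id = character(), x = numeric(),
                      y = numeric()))
  }
  do.call(rbind, out)
}

#' Per-bin cell counts over time
#'
#' At each sampled time point, counts the distinct tracks whose (linearly
#' interpolated) position falls in each concentric bin. Positions outside
#' the observation disc are excluded.
#'
#' @param trackset A [track_set].
#' @param geometry A [bead_geometry].
#' @param interval_s Sampling interval in s (default 60); must be a
#'   multiple of the track set's frame interval.
#' @return Data frame with columns `bin` (label), `time_s`, `value`
#'   (count), `n` (same count), and attribute `metric = "count"`.
#' @export
frame_bin_counts <- function(trackset, geometry, interval_s = 60) {
  stopifnot(inherits(trackset, "track_set"),
            inherits(geometry, "bead_geometry"), interval_s > 0)
  ratio <- interval_s / trackset$frame_interval
  if (abs(ratio - round(ratio)) > 1e-9) {
    stop("interval_s must be a multiple of the frame interval",
         call. = FALSE)
  }
  times <- seq(0, trackset$duration, by = interval_s)
  labels <- bin_labels(geometry)
  rows <- lapply(times, function(tp) {
    pos <- positions_at(trackset, tp)
    bins <- radial_bin(pos$x, pos$y, geometry)
    counts <- tabulate(bins, nbins = geometry$n_bins)
    data.frame(bin = labels, time_s = tp, value = counts, n = counts)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$bin, out$time_s), ]
  rownames(out) <- NULL
  attr(out, "metric") <- "count"
  out
}

#' Standardize count series to baseline-anchored Z-scores
#'
#' Standard-score normalization of per-bin cell counts: within each
#' population, `Z = (X - mu) / sigma` with `mu` and `sigma` (population
#' standard deviation) taken over all counts of that population pooled over
#' time points and replicates; then each individual series is shifted so
#' its value at `baseline_time` is exactly 0. A population with zero
#' variance yields all-zero output with a warning rather than an error.
#'
#' The population defaults to one treatment within one bin (columns
#' `treatment` and/or `replicate` are honoured when present: `treatment`
#' joins `bin` in defining the population, `replicate` defines separate
#' series for baseline anchoring).
#'
#' @param counts Data frame from [frame_bin_counts] (columns `bin`,
#'   `time_s`, `value`; optional `treatment`, `replicate`).
#' @param baseline_time Time point anchored to 0 (default 0); must be
#'   present in every series.
#' @param sd_type `"population"` (default) or `"sample"` standard
#'   deviation.
#' @return The input with `value` replaced by the baseline-anchored
#'   Z-score; attribute `metric = "normalized_count"`.
#' @export
#' @examples
#' x <- data.frame(bin = "A", time_s = c(0, 60, 120), value = c(2, 4, 6))
#' normalize_counts(x)$value  # 0, 1.225, 2.449
normalize_counts <- function(counts, baseline_time = 0,
                             sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  df <- as.data.frame(counts)
  stopifnot(all(c("bin", "time_s", "value") %in% names(df)))
  pop_cols <- intersect(c("treatment", "bin"), names(df))
  series_cols <- intersect(c("treatment", "bin", "replicate"), names(df))
  pop_key <- interaction(df[pop_cols], drop = TRUE)

  z <- df$value
  for (g in levels(pop_key)) {
    idx <- pop_key == g
    xs <- df$value[idx]
    mu <- mean(xs)
    sigma <- if (sd_type == "population") {
      sqrt(mean((xs - mu)^2))
    } else {
      stats::sd(xs)
    }
    if (!is.finite(sigma) || sigma == 0) {
      warning("population '", g, "' has zero variance; ",
              "normalized values set to 0", call. = FALSE)
      z[idx] <- 0
    } else {
      z[idx] <- (xs - mu) / sigma
    }
  }
  df$value <- z

  series_key <- interaction(df[series_cols], drop = TRUE)
  for (g in levels(series_key)) {
    idx <- series_key == g
    at_base <- idx & abs(df$time_s - baseline_time) < 1e-9
    if (!any(at_base)) {
      stop("baseline_time ", baseline_time,
           " missing from series '", g, "'", call. = FALSE)
    }
    df$value[idx] <- df$value[idx] - df$value[which(at_base)[1]]
  }
  attr(df, "metric") <- "normalized_count"
  df
}

#' Sine-angle orientation of a movement step
#'
#' Signed orientation of a step relative to the bead: the component of the
#' radial approach per unit path length, `(rho_from - rho_to) / step
#' length`, where `rho` is the distance to the bead centre. Bounded in
#' \[-1, 1\]; +1 for a step exactly at the bead, -1 exactly away, 0 for a
#' tangential step. Positive values mean the cell moved toward the bead.
#'
#' @param p_from,p_to Step endpoints: numeric `c(x, y)` vectors or
#'   two-column matrices (um).
#' @param bead_center Bead centre as `c(x, y)` (um).
#' @return Numeric vector of sine angles; `NA` for zero-length steps.
#' @export
#' @examples
#' step_sine_angle(c(100, 0), c(90, 0), c(0, 0))   # +1 (approach)
#' step_sine_angle(c(100, 0), c(100, 10), c(0, 0)) # ~ -0.05 (tangential)
step_sine_angle <- function(p_from, p_to, bead_center) {
  pf <- matrix(p_from, ncol = 2)
  pt <- matrix(p_to, ncol = 2)
  stopifnot(nrow(pf) == nrow(pt), length(bead_center) == 2)
  rho_from <- sqrt((pf[, 1] - bead_center[1])^2 +
                     (pf[, 2] - bead_center[2])^2)
  rho_to <- sqrt((pt[, 1] - bead_center[1])^2 +
                   (pt[, 2] - bead_center[2])^2)
  step_len <- sqrt(rowSums((pt - pf)^2))
  out <- (rho_from - rho_to) / step_len
  out[step_len == 0] <- NA_real_
  out
}

#' Internal: per-step table with sine angles, speeds, bins and windows
#' @noRd
step_table <- function(trackset, geometry, interval_s) {
  steps <- lapply(names(trackset$tracks), function(id) {
    tr <- trackset$tracks[[id]]
    st <- step_speeds(tr)
    n <- nrow(tr)
    st$sine <- step_sine_angle(
      cbind(tr$x[-n], tr$y[-n]), cbind(tr$x[-1], tr$y[-1]),
      c(geometry$bead_x, geometry$bead_y)
    )
    st$track_id <- id
    st
  })
  steps <- do.call(rbind, steps)
  steps$bin <- radial_bin(steps$x_mid, steps$y_mid, geometry)
  steps$window <- floor(steps$t_mid / interval_s)
  steps
}

#' Internal: per-(bin, window) mean of a step statistic with the
#' single-track exclusion rule
#' @noRd
binned_window_mean <- function(trackset, geometry, interval_s, stat_fun,
                               metric) {
  stopifnot(inherits(trackset, "track_set"),
            inherits(geometry, "bead_geometry"), interval_s > 0)
  steps <- step_table(trackset, geometry, interval_s)
  steps <- steps[!is.na(steps$bin), , drop = FALSE]
  labels <- bin_labels(geometry)
  windows <- seq(0, max(0, ceiling(trackset$duration / interval_s) - 1))
  grid <- expand.grid(bin_idx = seq_along(labels), window = windows)
  rows <- Map(function(b, w) {
    sel <- steps[steps$bin == b & steps$window == w, , drop = FALSE]
    n_tr <- length(unique(sel$track_id))
    vals <- stat_fun(sel)
    if (n_tr < 2) vals[] <- NA_real_  # single-track windows excluded
    data.frame(bin = labels[b], time_s = w * interval_s,
               as.list(vals), n = n_tr)
  }, grid$bin_idx, grid$window)
  out <- do.call(rbind, rows)
  out <- out[order(out$bin, out$time_s), ]
  rownames(out) <- NULL
  attr(out, "metric") <- metric
  out
}

#' Per-bin mean sine-angle orientation over time
#'
#' Assigns each movement step to the bin of its spatial midpoint and to the
#' time window containing its temporal midpoint, then averages the step
#' sine angles per (bin, window). Windows to which only a single track
#' contributes are reported as missing — one cell cannot represent a bin.
#'
#' @param trackset A [track_set].
#' @param geometry A [bead_geometry].
#' @param interval_s Window length in s (default 60).
#' @return Data frame with columns `bin`, `time_s` (window start), `value`
#'   (mean sine angle), `n` (contributing tracks); attribute
#'   `metric = "sine_angle"`.
#' @export
binned_mean_sine <- function(trackset, geometry, interval_s = 60) {
  binned_window_mean(
    trackset, geometry, interval_s,
    stat_fun = function(sel) {
      c(value = if (nrow(sel) == 0) NA_real_ else
        mean(sel$sine, na.rm = TRUE))
    },
    metric = "sine_angle"
  )
}

#' Per-bin sum of cell-to-bead distances over time
#'
#' At each sampled time point, sums the distance to the bead centre over
#' the cells present in each bin. A declining trend indicates net migration
#' toward the source. Rows with `bin = "total"` sum over all cells inside
#' the observation disc.
#'
#' @param trackset A [track_set].
#' @param geometry A [bead_geometry].
#' @param interval_s Sampling interval in s (default 60).
#' @param include_total Add the all-bin total series (default `TRUE`).
#' @return Data frame with columns `bin`, `time_s`, `value` (um), `n`
#'   (cells contributing); attribute `metric = "sum_distance"`.
#' @export
sum_distance_series <- function(trackset, geometry, interval_s = 60,
                                include_total = TRUE) {
  stopifnot(inherits(trackset, "track_set"),
            inherits(geometry, "bead_geometry"), interval_s > 0)
  times <- seq(0, trackset$duration, by = interval_s)
  labels <- bin_labels(geometry)
  rows <- lapply(times, function(tp) {
    pos <- positions_at(trackset, tp)
    rho <- bead_distance(pos$x, pos$y, geometry)
    bins <- radial_bin(pos$x, pos$y, geometry)
    per_bin <- vapply(seq_along(labels), function(b) {
      sum(rho[!is.na(bins) & bins == b])
    }, numeric(1))
    n_bin <- vapply(seq_along(labels), function(b) {
      sum(!is.na(bins) & bins == b)
    }, integer(1))
    out <- data.frame(bin = labels, time_s = tp, value = per_bin,
                      n = n_bin)
    if (include_total) {
      inside <- !is.na(bins)
      out <- rbind(out, data.frame(bin = "total", time_s = tp,
                                   value = sum(rho[inside]),
                                   n = sum(inside)))
    }
    out
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$bin, out$time_s), ]
  rownames(out) <- NULL
  attr(out, "metric") <- "sum_distance"
  out
}

#' Ordinary-least-squares trend of a time series
#'
#' Slope of `value` against `time_s` with the classical standard error,
#' t-statistic and two-sided p-value. The p-value is descriptive output
#' only: no correction for serial correlation or multiplicity is applied.
#'
#' @param series Data frame with columns `time_s` and `value`; missing
#'   values are dropped. At least 3 non-missing points required.
#' @return One-row data frame with `slope`, `se`, `t_stat`, `p_value`,
#'   `n`.
#' @export
#' @examples
#' trend_slope(data.frame(time_s = 0:10, value = 100 - 2 * (0:10)))$slope
trend_slope <- function(series) {
  df <- as.data.frame(series)
  stopifnot(all(c("time_s", "value") %in% names(df)))
  df <- df[is.finite(df$time_s) & is.finite(df$value), ]
  if (nrow(df) < 3) {
    stop("need at least 3 non-missing points for a trend", call. = FALSE)
  }
  fit <- stats::lm(value ~ time_s, data = df)
  cf <- summary(fit)$coefficients
  data.frame(
    slope = cf["time_s", "Estimate"],
    se = cf["time_s", "Std. Error"],
    t_stat = cf["time_s", "t value"],
    p_value = cf["time_s", "Pr(>|t|)"],
    n = nrow(df)
  )
}
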