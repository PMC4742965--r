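#' Per-bin windowed mean cell speed
#'
#' Step speeds are assigned to the bin of the step's spatial midpoint and
#' to the window containing its temporal midpoint; per (bin, window) the
#' mean raw speed and the mean `log(1 + speed)` (the variance-stabilizing
#' transform used for speed statistics) are reported over all contributing
#' steps. Windows with only a single contributing track are set to missing.
#'
#' @param trackset A [track_set].
#' @param geometry A [bead_geometry].
#' @param window_s Window length in s (default 30).
#' @return Data frame with columns `bin`, `time_s` (window start), `value`
#'   (mean speed, um/s), `value_log1p` (mean log(1+speed)), `n`
#'   (contributing tracks); attribute `metric = "speed"`.
#' @export
binned_mean_speed <- function(trackset, geometry, window_s = 30) {
  binned_window_mean(
    trackset, geometry, window_s,
    stat_fun = function(sel) {
      if (nrow(sel) == 0) {
        c(value = NA_real_, value_log1p = NA_real_)
      } else {
        c(value = mean(sel$speed),
          value_log1p = mean(log1p(sel$speed)))
      }
    },
    metric = "speed"
  )
}

#' Motile fraction from a two-frame overlay
#'
#' Classifies each cell as motile or immotile by overlaying two
#' observations of the same cells a short interval apart (15 s in the
#' standard assay): a cell whose displacement between the frames is at most
#' `tolerance_um` is immotile. The rows of the two frames must correspond
#' to the same cells in the same order.
#'
#' @param frame_a,frame_b Data frames (or 2-column matrices) of matched
#'   cell positions with columns/cols `x`, `y` (um).
#' @param tolerance_um Displacement at or below which a cell counts as
#'   immotile (default 1 um; "exactly the same position" is not robust to
#'   localization noise).
#' @return Fraction of motile cells in \[0, 1\].
#' @export
#' @examples
#' a <- data.frame(x = c(0, 0, 0), y = c(0, 0, 0))
#' b <- data.frame(x = c(0, 5, 12), y = c(0, 0, 0))
#' motile_fraction(a, b)  # 2/3
motile_fraction <- function(frame_a, frame_b, tolerance_um = 1) {
  a <- as.data.frame(frame_a)
  b <- as.data.frame(frame_b)
  if (is.null(names(a)) || !all(c("x", "y") %in% names(a))) {
    names(a)[1:2] <- c("x", "y")
  }
  if (is.null(names(b)) || !all(c("x", "y") %in% names(b))) {
    names(b)[1:2] <- c("x", "y")
  }
  if (nrow(a) != nrow(b)) {
    stop("frames must list the same cells: ", nrow(a), " vs ", nrow(b),
         " rows", call. = FALSE)
  }
  if (nrow(a) == 0) stop("no cells in the frames", call. = FALSE)
  stopifnot(is.numeric(tolerance_um), tolerance_um >= 0)
  disp <- sqrt((b$x - a$x)^2 + (b$y - a$y)^2)
  mean(disp > tolerance_um)
}
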