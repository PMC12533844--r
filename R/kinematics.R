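#' Per-frame kinematic series of a pose track
#'
#' Computes the standard trajectory metrics used throughout the pipeline, all
#' of length T (first-difference series are padded with 0 at frame 0):
#' \describe{
#'   \item{speed}{norm of the center-keypoint displacement between
#'     consecutive frames, converted to mm/s via the pixel size and frame
#'     rate.}
#'   \item{heading}{direction of the center-to-snout vector in degrees in the
#'     internal Cartesian frame (+x = 0, counter-clockwise positive), wrapped
#'     to (-180, 180].}
#'   \item{dheading}{instantaneous (per-frame) signed heading change, the
#'     wrapped first difference of heading, degrees per frame.}
#'   \item{tail_angle}{signed angle in degrees between the tailward trunk
#'     axis (snout-to-center direction) and the caudal-most segment
#'     (keypoint 7 to the tail tip, keypoint 8); 0 for a straight body.}
#' }
#' Frames with a masked snout, center or caudal keypoint propagate NA into
#' the series that depend on them.
#'
#' @param track a (cleaned) [pose_track()].
#' @return an object of class \code{kinematic_series}: a list of the four
#'   numeric series plus \code{fps} and \code{pixel_size}.
#' @export
kinematic_series <- function(track) {
  co <- track$coords
  T_ <- dim(co)[1]
  na_kp <- function(k) ifelse(track$missing[, k], NA_real_, 1)
  mm <- track$pixel_size / 1000   # mm per pixel

  ctr <- (co[, 4, 1] + 1i * co[, 4, 2]) * na_kp(4)
  snt <- (co[, 1, 1] + 1i * co[, 1, 2]) * na_kp(1)
  step <- c(0, Mod(diff(ctr)))
  speed <- step * mm * track$fps

  heading <- .wrap180(Arg(snt - ctr) * 180 / pi)
  dheading <- c(0, .wrap180(diff(heading)))

  trunk_tailward <- ctr - snt                     # points from head to tail
  caudal <- (co[, 8, 1] + 1i * co[, 8, 2]) * na_kp(8) -
            (co[, 7, 1] + 1i * co[, 7, 2]) * na_kp(7)
  tail_angle <- .wrap180((Arg(caudal) - Arg(trunk_tailward)) * 180 / pi)
  tail_angle[Mod(caudal) == 0 | Mod(trunk_tailward) == 0] <- NA_real_

  structure(list(speed = speed, heading = heading, dheading = dheading,
                 tail_angle = tail_angle, fps = track$fps,
                 pixel_size = track$pixel_size),
            class = "kinematic_series")
}

## wrap degrees to (-180, 180]
.wrap180 <- function(a) {
  out <- (a + 180) %% 360 - 180
  out[!is.na(out) & out == -180] <- 180
  out
}

#' @export
print.kinematic_series <- function(x, ...) {
  cat(sprintf("<kinematic_series> %d frames @ %g fps; max speed %.2f mm/s, max |dheading| %.1f deg/frame\n",
              length(x$speed), x$fps, max(x$speed, na.rm = TRUE),
              max(abs(x$dheading), na.rm = TRUE)))
  invisible(x)
}

#' Threshold-based movement bouts from the speed series
#'
#' A movement bout is a maximal run of frames with speed strictly above
#' \code{threshold} that lasts at least \code{min_frames} frames — the
#' classical 2 mm/s, >= 5 frame (31 ms at 160 fps) manual definition.
#'
#' @param series a [kinematic_series()] (or a bare numeric speed vector).
#' @param threshold speed threshold in mm/s; default 2.
#' @param min_frames minimum run length in frames (inclusive); default 5.
#' @return data.frame with 0-based half-open columns \code{start_frame},
#'   \code{end_frame}.
#' @export
detect_speed_bouts <- function(series, threshold = 2, min_frames = 5) {
  speed <- if (inherits(series, "kinematic_series")) series$speed else series
  above <- !is.na(speed) & speed > threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_frames
  data.frame(start_frame = starts[keep] - 1L, end_frame = ends[keep])
}

#' Interval maxima of a kinematic series
#'
#' For each half-open frame interval, the maximum of the absolute value (or
#' the signed maximum) of the series — e.g. the maximum |instantaneous
#' heading change| in the 200 ms (32 frames at 160 fps) before, at and after
#' a stimulus.
#'
#' @param x numeric series (per frame).
#' @param intervals data.frame with 0-based half-open \code{start_frame},
#'   \code{end_frame} columns, or a list of length-2 vectors.
#' @param signed if TRUE take the signed maximum instead of max |x|.
#' @return numeric vector, one maximum per interval.
#' @export
interval_max <- function(x, intervals, signed = FALSE) {
  if (is.data.frame(intervals)) {
    iv <- Map(c, intervals$start_frame, intervals$end_frame)
  } else iv <- intervals
  vapply(iv, function(b) {
    if (b[2] <= b[1]) stop("empty interval [", b[1], ", ", b[2], ")")
    if (b[1] < 0 || b[2] > length(x))
      stop("interval [", b[1], ", ", b[2], ") outside series of length ",
           length(x))
    v <- x[(b[1] + 1):b[2]]
    if (signed) max(v, na.rm = TRUE) else max(abs(v), na.rm = TRUE)
  }, numeric(1))
}

#' Annotate bouts with kinematic summaries
#'
#' Adds per-bout duration (ms), maximum speed (mm/s) and maximum
#' |instantaneous heading change| (degrees/frame), each computed over the
#' bout's own frames.
#'
#' @param bouts data.frame with 0-based half-open \code{start_frame},
#'   \code{end_frame} columns (e.g. from [extract_bouts()] or
#'   [detect_speed_bouts()]).
#' @param series a [kinematic_series()] for the same track.
#' @return \code{bouts} with columns \code{duration_ms},
#'   \code{max_speed_mm_s}, \code{max_abs_dheading_deg} added.
#' @export
annotate_bouts <- function(bouts, series) {
  if (!nrow(bouts)) {
    bouts$duration_ms <- numeric(0)
    bouts$max_speed_mm_s <- numeric(0)
    bouts$max_abs_dheading_deg <- numeric(0)
    return(bouts)
  }
  iv <- bouts[, c("start_frame", "end_frame")]
  bouts$duration_ms <- (bouts$end_frame - bouts$start_frame) / series$fps * 1000
  bouts$max_speed_mm_s <- interval_max(series$speed, iv)
  bouts$max_abs_dheading_deg <- interval_max(series$dheading, iv)
  bouts
}
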