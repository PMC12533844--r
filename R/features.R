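#' Slice a pose track into overlapping behavior windows
#'
#' A behavior window is a fixed-length slice of W consecutive frames (default
#' 40, i.e. 250 ms at 160 fps) treated as one classification unit. A track of
#' T frames yields exactly \code{T - W} windows with 0-based start frames
#' \code{0 .. T-W-1} (windows are half-open \code{[start, start+W)}); a
#' 1600-frame acquisition therefore yields 1560 windows. Windows containing
#' any masked keypoint are marked unusable and are excluded from
#' normalization statistics and inference.
#'
#' @param track a [pose_track()].
#' @param W window width in frames; default 40.
#' @return an object of class \code{behavior_windows}: list with \code{coords}
#'   (n x W x 8 x 2 array, internal Cartesian pixels), \code{starts} (0-based),
#'   \code{usable}, \code{aligned} flag, and the track's \code{fps},
#'   \code{pixel_size} and \code{plate_format}.
#' @export
make_windows <- function(track, W = 40) {
  T_ <- n_frames(track)
  if (T_ <= W)
    stop("track too short: ", T_, " frames; at least ", W + 1,
         " frames are required for W = ", W)
  n <- T_ - W
  starts <- seq_len(n) - 1L
  idx <- outer(starts, seq_len(W), `+`)  # n x W frame indices (1-based)
  co <- array(track$coords[as.vector(idx), , ], c(n, W, 8, 2))
  any_missing_frame <- rowSums(track$missing) > 0
  usable <- rowSums(matrix(any_missing_frame[as.vector(idx)], n, W)) == 0
  structure(list(coords = co, starts = starts, usable = usable,
                 aligned = FALSE, W = W, fps = track$fps,
                 pixel_size = track$pixel_size,
                 plate_format = track$plate_format),
            class = "behavior_windows")
}

#' @export
print.behavior_windows <- function(x, ...) {
  cat(sprintf("<behavior_windows> %d windows of %d frames (%s), %d usable\n",
              length(x$starts), x$W,
              if (x$aligned) "egocentrically aligned" else "unaligned",
              sum(x$usable)))
  invisible(x)
}

#' Egocentrically align behavior windows
#'
#' For each window, one rigid transform is computed from its first frame: the
#' rotation that points the center-to-snout vector straight up (+y) followed
#' by the translation that moves the first frame's center keypoint to the
#' origin. That single transform is applied to all W frames, so the fish
#' starts every window at the origin pointing up and its subsequent motion is
#' expressed in this body-centered frame. All intra-frame pairwise distances
#' are preserved exactly (up to floating point). Windows whose first-frame
#' center and snout coincide have no defined heading; they are marked
#' unusable with a warning and left untransformed.
#'
#' @param windows a \code{behavior_windows} object from [make_windows()].
#' @return the windows, aligned (\code{aligned = TRUE}).
#' @export
egocentric_align <- function(windows) {
  if (windows$aligned) return(windows)
  co <- windows$coords
  n <- dim(co)[1]; W <- dim(co)[2]
  z <- array(co[, , , 1, drop = FALSE], c(n, W, 8)) +
    1i * array(co[, , , 2, drop = FALSE], c(n, W, 8))  # n x W x 8 complex
  ctr <- z[, 1, 4]                              # frame-0 center keypoint
  snt <- z[, 1, 1]                              # frame-0 snout
  head_vec <- snt - ctr
  degen <- Mod(head_vec) == 0
  if (any(degen)) {
    warning(sum(degen), " window(s) have coincident center and snout in ",
            "frame 0; marked unusable")
    windows$usable[degen] <- FALSE
  }
  # rotation taking the heading to +y (angle pi/2): multiply by
  # exp(i*(pi/2 - arg(head_vec))); rotate about frame-0 center, then drop
  # the center at the origin.
  rot <- ifelse(degen, 1 + 0i, complex(modulus = 1,
                                       argument = pi / 2 - Arg(head_vec)))
  zc <- (z - array(ctr, dim(z))) * array(rot, dim(z))
  zc[degen, , ] <- z[degen, , ]
  out <- co
  out[, , , 1] <- Re(zc)
  out[, , , 2] <- Im(zc)
  windows$coords <- out
  windows$aligned <- TRUE
  windows
}

## flattening order: timepoint-major, then keypoint, then (x, y);
## index of (t, k, c) is ((t-1)*8 + (k-1))*2 + c.
.flatten_windows <- function(co) {
  n <- dim(co)[1]
  matrix(aperm(co, c(4, 3, 2, 1)), nrow = n, byrow = TRUE)
}

#' Reshape flat feature vectors back into window arrays
#'
#' Inverse of the flattening used by [featurize()] (before normalization):
#' row-vectors of length W*8*2 become an n x W x 8 x 2 array.
#'
#' @param vectors n x (W*8*2) numeric matrix.
#' @param W window width in frames.
#' @return n x W x 8 x 2 array.
#' @export
unflatten_windows <- function(vectors, W = 40) {
  n <- nrow(vectors)
  aperm(array(t(vectors), c(2, 8, W, n)), c(4, 3, 2, 1))
}

#' Flatten and normalize aligned windows into a feature matrix
#'
#' Each aligned window is flattened (timepoint-major, then keypoint, then
#' x, y) to a vector of length W*8*2 — 640 for the default 40-frame window —
#' and normalized with two dataset-level scalars: every value is divided by
#' \code{norm_max}, the maximum absolute coordinate over the usable windows,
#' and then \code{norm_mean}, the mean of the max-scaled values, is
#' subtracted. The constants differ between plate formats (larger wells span
#' more pixels), so they are frozen at training time and shipped inside the
#' classifier; passing \code{stats} reapplies training-time scaling at
#' inference.
#'
#' @param windows aligned \code{behavior_windows}.
#' @param stats optional list with \code{norm_max} and \code{norm_mean} from a
#'   reference (training) dataset; if omitted both are computed from the
#'   usable windows here and stored in the result.
#' @return an object of class \code{feature_matrix}: \code{vectors}
#'   (n x W*8*2), \code{norm_max}, \code{norm_mean}, \code{window_starts},
#'   \code{usable}, \code{W}, \code{plate_format}.
#' @export
featurize <- function(windows, stats = NULL) {
  if (!isTRUE(windows$aligned))
    stop("windows must be egocentrically aligned before featurizing")
  flat <- .flatten_windows(windows$coords)
  if (is.null(stats)) {
    use <- flat[windows$usable, , drop = FALSE]
    if (!nrow(use)) stop("no usable windows to compute normalization stats")
    norm_max <- max(abs(use))
    if (norm_max == 0)
      stop("normalization error: all coordinates are zero")
    norm_mean <- mean(use / norm_max)
  } else {
    norm_max <- stats$norm_max
    norm_mean <- stats$norm_mean
    if (!is.numeric(norm_max) || norm_max <= 0)
      stop("normalization error: stats$norm_max must be positive")
  }
  structure(list(vectors = flat / norm_max - norm_mean,
                 norm_max = norm_max, norm_mean = norm_mean,
                 window_starts = windows$starts, usable = windows$usable,
                 W = windows$W, plate_format = windows$plate_format),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d x %d (norm_max = %.4g, norm_mean = %.4g)\n",
              nrow(x$vectors), ncol(x$vectors), x$norm_max, x$norm_mean))
  invisible(x)
}
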