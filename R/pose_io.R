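#' Construct a pose track
#'
#' A pose track is the pipeline's universal input: per-frame coordinates of 8
#' anatomical keypoints (index 1 = snout, 4 = body center, 8 = caudal tail
#' tip) for one fish in one well, plus the acquisition metadata every
#' downstream stage needs (frame rate, spatial scale, plate format, stimulus
#' events).
#'
#' Coordinates are held internally in a right-handed Cartesian frame in pixel
#' units: \code{x} is the image column and \code{y} the negated image row, so
#' that "up in the well image" is +y. [read_pose_track()] and
#' [write_pose_track()] convert to and from the on-disk image (row, col)
#' convention; code constructing tracks directly (e.g. the simulator) supplies
#' Cartesian coordinates.
#'
#' @param coords numeric array of dimension \code{c(frames, 8, 2)}; internal
#'   Cartesian pixel coordinates, last dimension ordered (x, y).
#' @param fps frames per second (Hz), > 0.
#' @param pixel_size microns per pixel, > 0.
#' @param plate_format well-plate format, 24 or 96.
#' @param well_id well identifier string.
#' @param body_length fish body length in mm, or \code{NA} if unknown.
#' @param events list of [stimulus_event()] objects.
#' @param missing logical frames x 8 matrix marking unobserved keypoints;
#'   masked coordinates may be NA.
#' @return an object of class \code{pose_track}.
#' @export
pose_track <- function(coords, fps, pixel_size, plate_format = 24,
                       well_id = "A1", body_length = NA_real_,
                       events = list(), missing = NULL) {
  coords <- unclass(coords)
  if (length(dim(coords)) != 3L || dim(coords)[2] != 8L || dim(coords)[3] != 2L)
    stop("schema error: coords must be a frames x 8 keypoints x 2 array, got dims [",
         paste(dim(coords), collapse = ", "), "]")
  n <- dim(coords)[1]
  if (is.null(missing)) missing <- matrix(FALSE, n, 8)
  missing <- matrix(as.logical(missing), n, 8)
  if (!is.numeric(fps) || length(fps) != 1L || fps <= 0)
    stop("format error: fps must be a single positive number")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("format error: pixel_size must be a single positive number (um/px)")
  if (!plate_format %in% c(24, 96))
    stop("format error: plate_format must be 24 or 96")
  bad <- !is.finite(coords) & !array(missing, dim(coords))
  if (any(bad))
    stop("format error: non-finite coordinates at unmasked keypoints (first at frame ",
         which(apply(bad, 1, any))[1], ")")
  if (length(events) && !all(vapply(events, inherits, TRUE, "stimulus_event")))
    stop("format error: events must be a list of stimulus_event objects")
  structure(list(coords = coords, missing = missing, fps = fps,
                 pixel_size = pixel_size, plate_format = plate_format,
                 well_id = as.character(well_id),
                 body_length = as.numeric(body_length), events = events),
            class = "pose_track")
}

#' @export
print.pose_track <- function(x, ...) {
  cat(sprintf("<pose_track> %d frames @ %g fps (%.2f s), %d-well plate, well %s\n",
              n_frames(x), x$fps, n_frames(x) / x$fps, x$plate_format, x$well_id))
  cat(sprintf("  pixel size %g um/px; body length %s mm; %d masked keypoints; %d stimulus event(s)\n",
              x$pixel_size,
              ifelse(is.na(x$body_length), "?", format(x$body_length)),
              sum(x$missing), length(x$events)))
  invisible(x)
}

#' Number of frames in a pose track
#' @param track a [pose_track()].
#' @return integer frame count.
#' @export
n_frames <- function(track) dim(track$coords)[1]

#' Construct a stimulus event
#'
#' @param kind "acoustic" (plate tap) or "visual" (light-off).
#' @param onset seconds from acquisition start, >= 0.
#' @param duration stimulus duration in seconds; defaults to the assay values
#'   of 0.1 s for the tap and 2.0 s for the light-off period.
#' @return an object of class \code{stimulus_event}.
#' @export
stimulus_event <- function(kind = c("acoustic", "visual"), onset,
                           duration = NULL) {
  kind <- match.arg(kind)
  if (!is.numeric(onset) || length(onset) != 1L || onset < 0)
    stop("format error: onset must be a single non-negative number of seconds")
  if (is.null(duration))
    duration <- if (kind == "acoustic") 0.1 else 2.0
  structure(list(kind = kind, onset = onset, duration = duration),
            class = "stimulus_event")
}

## on-disk (row, col) <-> internal Cartesian (x = col, y = -row)
.cart_to_rowcol <- function(coords) {
  out <- coords
  out[, , 1] <- -coords[, , 2]   # row = -y
  out[, , 2] <- coords[, , 1]    # col = x
  out
}
.rowcol_to_cart <- function(rc) {
  out <- rc
  out[, , 1] <- rc[, , 2]        # x = col
  out[, , 2] <- -rc[, , 1]       # y = -row
  out
}

.events_to_df <- function(events) {
  if (!length(events))
    return(data.frame(kind = character(), onset_s = numeric(),
                      duration_s = numeric()))
  data.frame(kind = vapply(events, `[[`, "", "kind"),
             onset_s = vapply(events, `[[`, 0, "onset"),
             duration_s = vapply(events, `[[`, 0, "duration"))
}
.events_from_df <- function(df) {
  lapply(seq_len(nrow(df)), function(i)
    stimulus_event(df$kind[i], df$onset_s[i], df$duration_s[i]))
}

#' Write a pose track to disk
#'
#' Two dialects are supported. \code{"hdf5"} stores dataset \code{coords}
#' (frame x keypoint x coord, image row/col order), boolean dataset
#' \code{missing}, scalar attributes (\code{fps}, \code{pixel_size_um},
#' \code{plate_format}, \code{well_id}, \code{body_length_mm}) and an
#' \code{events} group. \code{"csv"} writes a long-form table with columns
#' \code{acquisition_id, frame, keypoint, row_px, col_px, missing} plus a
#' sidecar JSON (same path with extension \code{.json}) holding metadata and
#' events. Frames and keypoints are written 0-based.
#'
#' @param track a [pose_track()].
#' @param path output file path.
#' @param dialect "hdf5" or "csv".
#' @return \code{path}, invisibly.
#' @export
write_pose_track <- function(track, path, dialect = c("hdf5", "csv")) {
  dialect <- match.arg(dialect)
  rc <- .cart_to_rowcol(track$coords)
  if (dialect == "hdf5") {
    if (file.exists(path)) unlink(path)
    rhdf5::h5createFile(path)
    rhdf5::h5write(rc, path, "coords")
    rhdf5::h5write(track$missing * 1L, path, "missing")
    fid <- rhdf5::H5Fopen(path)
    on.exit(rhdf5::H5Fclose(fid), add = TRUE)
    rhdf5::h5writeAttribute(track$fps, fid, "fps")
    rhdf5::h5writeAttribute(track$pixel_size, fid, "pixel_size_um")
    rhdf5::h5writeAttribute(as.integer(track$plate_format), fid, "plate_format")
    rhdf5::h5writeAttribute(track$well_id, fid, "well_id")
    rhdf5::h5writeAttribute(as.numeric(track$body_length), fid, "body_length_mm")
    rhdf5::h5closeAll(fid)
    on.exit(NULL)
    rhdf5::h5write(.events_to_df(track$events), path, "events")
  } else {
    n <- n_frames(track)
    df <- data.frame(
      acquisition_id = track$well_id,
      frame = rep(seq_len(n) - 1L, each = 8L),
      keypoint = rep(0:7, n),
      # %.17g so coordinates survive the text round-trip bit-exactly
      row_px = sprintf("%.17g", as.vector(t(rc[, , 1]))),
      col_px = sprintf("%.17g", as.vector(t(rc[, , 2]))),
      missing = as.integer(as.vector(t(track$missing))))
    utils::write.csv(df, path, row.names = FALSE)
    meta <- list(fps = track$fps, pixel_size_um = track$pixel_size,
                 plate_format = track$plate_format, well_id = track$well_id,
                 body_length_mm = track$body_length,
                 events = .events_to_df(track$events))
    jsonlite::write_json(meta, .sidecar_path(path), auto_unbox = TRUE,
                         digits = NA, na = "null")
  }
  invisible(path)
}

.sidecar_path <- function(path) paste0(sub("\\.csv$", "", path), ".json")

#' Read a pose track from disk
#'
#' Reads either dialect written by [write_pose_track()], validates the schema
#' (exactly 8 keypoints per frame, positive fps and pixel size) and returns a
#' [pose_track()] with coordinates converted to the internal Cartesian frame.
#' Masked keypoints are recorded in the missing mask, never dropped.
#'
#' @param path input file path.
#' @param dialect "hdf5" or "csv".
#' @return a [pose_track()].
#' @export
read_pose_track <- function(path, dialect = c("hdf5", "csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("format error: file not found: ", path)
  if (dialect == "hdf5") {
    rc <- rhdf5::h5read(path, "coords")
    if (length(dim(rc)) != 3L || dim(rc)[2] != 8L)
      stop("schema error: coords must have 8 keypoints per frame, got ",
           dim(rc)[2])
    missing <- rhdf5::h5read(path, "missing") != 0
    att <- rhdf5::h5readAttributes(path, "/")
    ev <- tryCatch(rhdf5::h5read(path, "events"), error = function(e) NULL)
    events <- if (is.null(ev) || !nrow(ev)) list() else .events_from_df(ev)
    rhdf5::h5closeAll()
    pose_track(.rowcol_to_cart(rc), fps = as.numeric(att$fps),
               pixel_size = as.numeric(att$pixel_size_um),
               plate_format = as.numeric(att$plate_format),
               well_id = as.character(att$well_id),
               body_length = as.numeric(att$body_length_mm),
               events = events, missing = matrix(missing, dim(rc)[1], 8))
  } else {
    df <- utils::read.csv(path)
    need <- c("acquisition_id", "frame", "keypoint", "row_px", "col_px", "missing")
    miss <- setdiff(need, names(df))
    if (length(miss))
      stop("format error: CSV missing required column '", miss[1], "'")
    kp_per_frame <- table(df$frame)
    if (any(kp_per_frame != 8L))
      stop("schema error: every frame must have exactly 8 keypoints; frame ",
           names(kp_per_frame)[which(kp_per_frame != 8L)[1]], " has ",
           kp_per_frame[which(kp_per_frame != 8L)[1]])
    df <- df[order(df$frame, df$keypoint), ]
    n <- length(unique(df$frame))
    rc <- array(NA_real_, c(n, 8, 2))
    rc[, , 1] <- matrix(df$row_px, n, 8, byrow = TRUE)
    rc[, , 2] <- matrix(df$col_px, n, 8, byrow = TRUE)
    missing <- matrix(df$missing != 0, n, 8, byrow = TRUE)
    sp <- .sidecar_path(path)
    if (!file.exists(sp))
      stop("format error: metadata sidecar not found: ", sp)
    meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
    events <- if (is.null(meta$events) || !NROW(meta$events)) list()
              else .events_from_df(as.data.frame(meta$events))
    pose_track(.rowcol_to_cart(rc), fps = meta$fps,
               pixel_size = meta$pixel_size_um,
               plate_format = meta$plate_format, well_id = meta$well_id,
               body_length = ifelse(is.null(meta$body_length_mm), NA_real_,
                                    as.numeric(meta$body_length_mm)),
               events = events, missing = missing)
  }
}

#' Interpolate short tracking gaps
#'
#' Masked keypoints inside gaps of at most \code{max_gap} consecutive frames
#' are filled by per-coordinate linear interpolation between the flanking
#' observed frames and unmasked; longer gaps (and gaps touching the start or
#' end of the acquisition) stay masked, and windows overlapping them are
#' flagged unusable downstream. Non-masked coordinates are never altered.
#'
#' @param track a [pose_track()].
#' @param max_gap longest gap (frames) that will be interpolated; default 5.
#' @return a cleaned [pose_track()].
#' @export
clean_track <- function(track, max_gap = 5) {
  coords <- track$coords
  missing <- track$missing
  n <- dim(coords)[1]
  for (k in 1:8) {
    m <- missing[, k]
    if (!any(m)) next
    if (all(m)) {
      warning("keypoint ", k - 1L, " is masked on every frame; left unchanged")
      next
    }
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      len <- r$lengths[j]
      a <- starts[j] - 1L; b <- ends[j] + 1L   # flanking observed frames
      if (len > max_gap || a < 1L || b > n) next
      w <- seq_len(len) / (len + 1)
      for (d in 1:2)
        coords[starts[j]:ends[j], k, d] <-
          (1 - w) * coords[a, k, d] + w * coords[b, k, d]
      missing[starts[j]:ends[j], k] <- FALSE
    }
  }
  track$coords <- coords
  track$missing <- missing
  track
}
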