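#' Mean implied swim speed of each behavior window
#'
#' Mean per-frame center-keypoint displacement inside the window converted to
#' mm/s. Rigid alignment preserves distances, so the value is identical for
#' aligned and unaligned windows.
#'
#' @param windows a \code{behavior_windows} object.
#' @return numeric vector, mm/s per window (NA where coordinates are masked).
#' @export
window_mean_speed <- function(windows) {
  co <- windows$coords
  n <- dim(co)[1]; W <- dim(co)[2]
  cx <- array(co[, , 4, 1, drop = FALSE], c(n, W))
  cy <- array(co[, , 4, 2, drop = FALSE], c(n, W))
  step <- sqrt((cx[, -1, drop = FALSE] - cx[, -W, drop = FALSE])^2 +
               (cy[, -1, drop = FALSE] - cy[, -W, drop = FALSE])^2)
  rowMeans(step) * windows$fps * windows$pixel_size / 1000
}

#' Cluster behavior windows for candidate-bout discovery
#'
#' Unsupervised stage of the semi-supervised workflow: KMeans (default k = 9)
#' on the normalized feature vectors. The clusters are not nameable behaviors
#' — they separate stationary periods from movement, which is what makes
#' targeted clip export for manual labeling efficient. Roles are assigned by
#' [assign_roles()] when windows are supplied.
#'
#' @param features a \code{feature_matrix}.
#' @param k number of clusters; default 9.
#' @param seed RNG seed (multi-start Lloyd under this seed is deterministic).
#' @param windows optional \code{behavior_windows} matching \code{features};
#'   if given, cluster roles (stationary vs movement) are assigned.
#' @param speed_threshold role threshold in mm/s passed to [assign_roles()].
#' @return object of class \code{bout_clusters}: \code{k}, \code{centroids},
#'   \code{assignment} (per window, NA where unusable), \code{starts},
#'   \code{W}, \code{seed}, and \code{roles} (if assigned).
#' @export
fit_clusters <- function(features, k = 9, seed = 1, windows = NULL,
                         speed_threshold = 2) {
  x <- features$vectors[features$usable, , drop = FALSE]
  if (nrow(x) < k)
    stop("insufficient data: ", nrow(x), " usable windows for k = ", k)
  set.seed(seed)
  km <- stats::kmeans(x, centers = k, nstart = 10, iter.max = 100)
  assignment <- rep(NA_integer_, length(features$usable))
  assignment[features$usable] <- km$cluster
  out <- structure(list(k = k, centroids = km$centers,
                        assignment = assignment,
                        starts = features$window_starts, W = features$W,
                        seed = seed, roles = NULL),
                   class = "bout_clusters")
  if (!is.null(windows))
    out$roles <- assign_roles(out, windows, speed_threshold)
  out
}

#' @export
print.bout_clusters <- function(x, ...) {
  cat(sprintf("<bout_clusters> k = %d over %d windows\n",
              x$k, sum(!is.na(x$assignment))))
  if (!is.null(x$roles))
    cat("  roles:", paste(sprintf("%d=%s", seq_along(x$roles), x$roles),
                          collapse = ", "), "\n")
  invisible(x)
}

#' Assign stationary/movement roles to clusters
#'
#' Clusters whose mean implied center-keypoint speed is strictly below the
#' threshold (default 2 mm/s, the same threshold that defines manual speed
#' bouts) are stationary; all others are movement. If thresholding leaves a
#' role empty, the extreme cluster (slowest or fastest mean speed) is
#' reassigned so both roles are always represented.
#'
#' @param model a \code{bout_clusters}.
#' @param windows the \code{behavior_windows} the clustered features came
#'   from.
#' @param speed_threshold mm/s; default 2.
#' @return character vector of length k, values "stationary"/"movement".
#' @export
assign_roles <- function(model, windows, speed_threshold = 2) {
  sp <- window_mean_speed(windows)
  mean_sp <- vapply(seq_len(model$k), function(cl)
    mean(sp[which(model$assignment == cl)], na.rm = TRUE), numeric(1))
  roles <- ifelse(mean_sp < speed_threshold, "stationary", "movement")
  if (!any(roles == "stationary")) roles[which.min(mean_sp)] <- "stationary"
  if (!any(roles == "movement")) roles[which.max(mean_sp)] <- "movement"
  roles
}

#' Export candidate windows as clip files for manual labeling
#'
#' Samples windows from a requested role or cluster (optionally restricted to
#' starts near a frame of interest, e.g. the stimulus frame 800 of a
#' 1600-frame acquisition) and writes each as a small pose-track CSV clip,
#' plus a labels-template CSV to fill in during manual review.
#'
#' @param track the source [pose_track()].
#' @param clusters a \code{bout_clusters} with roles assigned.
#' @param dir output directory (created if needed).
#' @param role "stationary" or "movement"; alternative to \code{cluster}.
#' @param cluster specific cluster index (1..k); overrides \code{role}.
#' @param n number of clips to sample; if fewer match, all are exported with
#'   a warning.
#' @param seed sampling seed.
#' @param near_frame optional 0-based frame; only windows whose start lies
#'   within \code{near_width} frames of it are candidates.
#' @param near_width half-width in frames for \code{near_frame}; default 80.
#' @return character vector of clip file paths (invisibly).
#' @export
export_clips <- function(track, clusters, dir, role = "movement",
                         cluster = NULL, n = 5, seed = 1,
                         near_frame = NULL, near_width = 80) {
  if (is.null(clusters$roles) && is.null(cluster))
    stop("clusters has no roles; run assign_roles() or pass cluster=")
  cand <- if (!is.null(cluster)) which(clusters$assignment == cluster)
          else which(clusters$roles[clusters$assignment] == role)
  if (!is.null(near_frame))
    cand <- cand[abs(clusters$starts[cand] - near_frame) <= near_width]
  if (length(cand) < n) {
    warning("only ", length(cand), " matching window(s); exporting all")
    pick <- cand
  } else {
    set.seed(seed)
    pick <- sort(sample(cand, n))
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  rows <- list()
  for (i in pick) {
    s <- clusters$starts[i]
    fr <- (s + 1):(s + clusters$W)
    clip <- pose_track(track$coords[fr, , , drop = FALSE], fps = track$fps,
                       pixel_size = track$pixel_size,
                       plate_format = track$plate_format,
                       well_id = track$well_id,
                       body_length = track$body_length,
                       missing = track$missing[fr, , drop = FALSE])
    cl <- clusters$assignment[i]
    f <- file.path(dir, sprintf("%s_start%04d_cluster%d.csv",
                                track$well_id, s, cl))
    write_pose_track(clip, f, "csv")
    paths <- c(paths, f)
    rows[[length(rows) + 1L]] <- data.frame(file = basename(f),
                                            start_frame = s, cluster = cl,
                                            label = "")
  }
  tmpl <- if (length(rows)) do.call(rbind, rows)
          else data.frame(file = character(), start_frame = integer(),
                          cluster = integer(), label = character())
  utils::write.csv(tmpl, file.path(dir, "labels_template.csv"),
                   row.names = FALSE)
  invisible(paths)
}
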