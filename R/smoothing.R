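#' Majority voting: window labels to per-frame calls
#'
#' A sliding-window classifier emits one label per window start, so a single
#' timepoint is covered by up to W windows and raw output can flicker
#' frame-to-frame in ways no real fish moves. Majority voting aggregates, for
#' each frame t, the labels of every window overlapping t (starts in
#' \code{[t-W+1, t]}, clipped to the valid range) and keeps the most frequent
#' call. This aligns calls to real time and removes isolated single-window
#' flips; any displacement it introduces is under one window width (250 ms at
#' the default W = 40, 160 fps). Ties break toward the earlier label in
#' \code{classes} (stationary first — the least eventful call). Windows
#' labeled \code{"unknown"} do not vote; frames with no votes are
#' \code{"unknown"}.
#'
#' @param window_labels character vector of per-window labels, ordered by
#'   window start.
#' @param W window width in frames.
#' @param T_ total frame count of the acquisition.
#' @param classes ordered class labels (tie-break order), e.g. [class_set()].
#' @param starts 0-based window starts; default \code{0:(length-1)}.
#' @param fps frames per second, stored for downstream bout durations
#'   (optional).
#' @return object of class \code{frame_labels}: \code{labels} (length T_),
#'   \code{margin} (winner votes minus runner-up votes, 0 where unknown),
#'   \code{W}, \code{T}, \code{fps}.
#' @export
majority_vote <- function(window_labels, W, T_, classes, starts = NULL,
                          fps = NULL) {
  n <- length(window_labels)
  if (is.null(starts)) starts <- seq_len(n) - 1L
  if (any(starts < 0 | starts > T_ - W))
    stop("window starts must lie in [0, T-W]")
  K <- length(classes)
  code <- match(window_labels, classes)      # NA for "unknown"
  ind <- matrix(0L, T_, K)
  ok <- !is.na(code)
  if (any(ok))
    ind[cbind(starts[ok] + 1L, code[ok])] <-
      ind[cbind(starts[ok] + 1L, code[ok])] + 1L
  # handle duplicate starts (shouldn't occur, but keep counting exact)
  if (anyDuplicated(starts[ok])) {
    ind <- matrix(0L, T_, K)
    for (i in which(ok)) {
      ind[starts[i] + 1L, code[i]] <- ind[starts[i] + 1L, code[i]] + 1L
    }
  }
  cum <- rbind(matrix(0L, 1, K), apply(ind, 2, cumsum))
  t_idx <- seq_len(T_)                        # frame t = t_idx - 1
  hi <- pmin(t_idx, T_)                       # starts <= t  -> cum row t+1
  lo <- pmax(t_idx - W, 0L)                   # starts >= t-W+1 -> cum row t-W+1
  counts <- cum[hi + 1L, , drop = FALSE] - cum[lo + 1L, , drop = FALSE]
  any_vote <- rowSums(counts) > 0
  win <- max.col(counts, ties.method = "first")
  labels <- ifelse(any_vote, classes[win], "unknown")
  top <- counts[cbind(t_idx, win)]
  rest <- counts
  rest[cbind(t_idx, win)] <- -1L
  runner <- apply(rest, 1, max)
  margin <- ifelse(any_vote, top - pmax(runner, 0L), 0L)
  structure(list(labels = labels, margin = as.integer(margin), W = W,
                 T = T_, fps = fps),
            class = "frame_labels")
}

#' @export
print.frame_labels <- function(x, ...) {
  tb <- table(x$labels)
  cat(sprintf("<frame_labels> %d frames (W = %d): %s\n", x$T, x$W,
              paste(sprintf("%s %d", names(tb), tb), collapse = ", ")))
  invisible(x)
}

#' Segment per-frame calls into bouts
#'
#' A bout is a maximal run of identical consecutive calls whose length
#' strictly exceeds \code{min_run} frames (default 5 — runs of exactly 5 do
#' not qualify). Shorter runs and \code{"unknown"} frames become unlabeled
#' gaps; they are never merged into neighboring bouts, and a bout never spans
#' an unknown frame. Bouts plus gaps exactly partition the acquisition.
#'
#' @param frame_labels a \code{frame_labels} object from [majority_vote()]
#'   (or a bare character vector of per-frame calls).
#' @param min_run strict lower bound on run length in frames; default 5.
#' @param fps frames per second for durations; taken from
#'   \code{frame_labels} when present.
#' @param include_stationary keep stationary bouts in the table (default
#'   TRUE); movement-only analyses subset on \code{label}.
#' @return data.frame with columns \code{label}, 0-based half-open
#'   \code{start_frame}, \code{end_frame}, and \code{duration_ms} when fps is
#'   known.
#' @export
extract_bouts <- function(frame_labels, min_run = 5, fps = NULL,
                          include_stationary = TRUE) {
  if (inherits(frame_labels, "frame_labels")) {
    if (is.null(fps)) fps <- frame_labels$fps
    labels <- frame_labels$labels
  } else labels <- as.character(frame_labels)
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$lengths > min_run & r$values != "unknown"
  if (!include_stationary) keep <- keep & r$values != "stationary"
  out <- data.frame(label = r$values[keep], start_frame = starts[keep],
                    end_frame = ends[keep], stringsAsFactors = FALSE)
  if (!is.null(fps))
    out$duration_ms <- (out$end_frame - out$start_frame) / fps * 1000
  out
}

#' Keep bouts overlapping a frame interval
#'
#' Used for stimulus-locked analyses, e.g. bouts intersecting the 5.0-5.25 s
#' tap window (frames [800, 840) at 160 fps). Intervals are half-open; a bout
#' ending exactly at the interval start does not overlap.
#'
#' @param bouts data.frame with \code{start_frame}, \code{end_frame}.
#' @param interval length-2 vector, half-open frame range
#'   \code{[start, end)}.
#' @return the overlapping subset of \code{bouts}.
#' @export
filter_bouts_by_interval <- function(bouts, interval) {
  bouts[bouts$start_frame < interval[2] & bouts$end_frame > interval[1], ,
        drop = FALSE]
}
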