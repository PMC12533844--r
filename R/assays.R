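#' Frame interval in which a stimulus response counts
#'
#' Acoustic startle has short latency: a response within 250 ms of the tap
#' counts. Visual (light-off) startle is slower: within 1.0 s of the light
#' turning off. Both windows start at the stimulus onset frame (closed left,
#' open right).
#'
#' @param event a [stimulus_event()].
#' @param fps frames per second.
#' @return length-2 integer vector, half-open 0-based frame range.
#' @export
response_window <- function(event, fps) {
  if (!inherits(event, "stimulus_event")) stop("event must be a stimulus_event")
  len_s <- switch(event$kind, acoustic = 0.25, visual = 1.0,
                  stop("unknown stimulus kind: ", event$kind))
  c(round(event$onset * fps), round((event$onset + len_s) * fps))
}

#' Did a trial respond to a stimulus?
#'
#' A trial counts as responsive when the elicited behavior (AsLB for
#' acoustic, VsLB for visual) was called inside the stimulus response window.
#' Mode \code{"frames"} requires at least one voted frame with the target
#' label inside the window; mode \code{"bouts"} requires a qualifying bout
#' (from [extract_bouts()]) overlapping it.
#'
#' @param frame_labels a \code{frame_labels} object (mode "frames").
#' @param event the [stimulus_event()] of the trial.
#' @param fps frames per second.
#' @param target_label label that counts as a response; default chosen from
#'   the stimulus kind (acoustic -> "AsLB", visual -> "VsLB").
#' @param mode "frames" (default) or "bouts".
#' @param bouts bout table, required for mode "bouts".
#' @return logical.
#' @export
trial_response <- function(frame_labels, event, fps = NULL,
                           target_label = NULL,
                           mode = c("frames", "bouts"), bouts = NULL) {
  mode <- match.arg(mode)
  if (is.null(fps)) fps <- frame_labels$fps
  if (is.null(fps)) stop("fps is required")
  if (is.null(target_label))
    target_label <- switch(event$kind, acoustic = "AsLB", visual = "VsLB")
  win <- response_window(event, fps)
  if (mode == "frames") {
    lab <- frame_labels$labels
    win[2] <- min(win[2], length(lab))
    if (win[1] >= win[2]) return(FALSE)
    any(lab[(win[1] + 1):win[2]] == target_label)
  } else {
    if (is.null(bouts)) stop("mode 'bouts' requires a bout table")
    hit <- filter_bouts_by_interval(bouts, win)
    any(hit$label == target_label)
  }
}

#' Trial- and fish-level response rates
#'
#' From a table of per-trial response flags: the trial-level rate is the
#' fraction of all trials with a response; the fish-level responder rate is
#' the fraction of fish with at least one responding trial (logical OR over
#' that fish's trials, typically 6 replicates).
#'
#' @param table data.frame with columns \code{fish_id}, \code{trial_id},
#'   \code{responded} (logical).
#' @return list with \code{trial_rate} and \code{fish_rate}, both in [0, 1].
#' @export
response_rates <- function(table) {
  if (!nrow(table)) stop("empty response table")
  trial_rate <- mean(table$responded)
  per_fish <- tapply(table$responded, table$fish_id, any)
  list(trial_rate = trial_rate, fish_rate = mean(per_fish))
}

#' Spontaneous-behavior summary of a bout table
#'
#' Per-class bout counts, each movement class's proportion among movement
#' bouts, movement bouts per second, and the fraction of recorded time spent
#' in movement bouts.
#'
#' @param bouts bout table from [extract_bouts()] (stationary rows allowed;
#'   they are excluded from the movement accounting).
#' @param total_frames total recorded frames.
#' @param fps frames per second.
#' @return list with \code{counts} (per class, movement classes),
#'   \code{proportions}, \code{bouts_per_second},
#'   \code{time_in_movement}.
#' @export
spontaneous_summary <- function(bouts, total_frames, fps) {
  mv <- bouts[!bouts$label %in% c("stationary", "unknown"), , drop = FALSE]
  counts <- table(mv$label)
  n <- sum(counts)
  proportions <- if (n > 0) as.numeric(counts) / n else numeric(length(counts))
  names(proportions) <- names(counts)
  total_s <- total_frames / fps
  list(counts = counts, proportions = proportions,
       bouts_per_second = n / total_s,
       time_in_movement = sum(mv$end_frame - mv$start_frame) / total_frames)
}

#' Run a stimulus-response assay over many trials
#'
#' Convenience wrapper: given per-trial frame labels and their stimulus
#' events, builds the response table and rates.
#'
#' @param trials list, one element per trial, each a list with
#'   \code{fish_id}, \code{trial_id}, \code{frame_labels}, \code{event}.
#' @param fps frames per second.
#' @param mode passed to [trial_response()].
#' @return list with \code{table} (data.frame) and the [response_rates()].
#' @export
response_assay <- function(trials, fps, mode = "frames") {
  tab <- do.call(rbind, lapply(trials, function(tr) {
    data.frame(fish_id = tr$fish_id, trial_id = tr$trial_id,
               stimulus = tr$event$kind,
               responded = trial_response(tr$frame_labels, tr$event, fps,
                                          mode = mode))
  }))
  c(list(table = tab), response_rates(tab))
}
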