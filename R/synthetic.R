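#' Archetype parameters for a synthetic behavior class
#'
#' Parameter ranges for the kinematic archetypes the simulator emits. The
#' defaults encode the qualitative ordering of the classes: scoots are
#' forward propulsion with little heading change; R-turns reorient heading
#' 30-90 degrees while staying nearly in place; acoustic-startle-like bouts
#' (C-start-like) exceed 90 degrees of heading change within ~40 ms at high
#' peak speed; visual-startle-like bouts (O-bend-like) make a comparable
#' heading change but over 100-250 ms at lower peak speed and longer latency.
#' All ranges are configurable; uniform sampling within a range.
#'
#' @param label one of "stationary", "scoot", "turn", "AsLB", "VsLB".
#' @param fps frames per second the frame-valued ranges assume; default 160.
#' @return object of class \code{archetype_params}: list with \code{label},
#'   \code{duration_range} (frames), \code{peak_speed_range} (mm/s),
#'   \code{dheading_range} (total heading change, degrees),
#'   \code{time_to_peak_range} (frames to complete the heading change),
#'   \code{tail_amp} (tail-beat amplitude, degrees),
#'   \code{latency_range} (s after a stimulus).
#' @export
archetype_params <- function(label = c("stationary", "scoot", "turn",
                                       "AsLB", "VsLB"),
                             fps = 160) {
  label <- match.arg(label)
  f <- fps / 160   # scale frame-valued defaults to other frame rates
  p <- switch(label,
    stationary = list(duration_range = c(16, 64), peak_speed_range = c(0, 0),
                      dheading_range = c(0, 0), time_to_peak_range = c(1, 1),
                      tail_amp = 0, latency_range = c(0, 0)),
    scoot = list(duration_range = c(16, 32), peak_speed_range = c(5, 20),
                 dheading_range = c(0, 25), time_to_peak_range = c(8, 16),
                 tail_amp = 25, latency_range = c(0.02, 0.1)),
    turn = list(duration_range = c(16, 32), peak_speed_range = c(1, 4),
                dheading_range = c(30, 90), time_to_peak_range = c(8, 16),
                tail_amp = 35, latency_range = c(0.02, 0.1)),
    AsLB = list(duration_range = c(10, 16), peak_speed_range = c(30, 60),
                dheading_range = c(95, 160), time_to_peak_range = c(3, 6),
                tail_amp = 100, latency_range = c(0.005, 0.02)),
    VsLB = list(duration_range = c(24, 34), peak_speed_range = c(12, 25),
                dheading_range = c(95, 160), time_to_peak_range = c(16, 28),
                tail_amp = 80, latency_range = c(0.15, 0.4)))
  for (fld in c("duration_range", "time_to_peak_range"))
    p[[fld]] <- pmax(1, round(p[[fld]] * f))
  structure(c(list(label = label), p), class = "archetype_params")
}

#' Simulator configuration
#'
#' The stated world of the synthetic acquisitions: 160 fps for 10 s (1600
#' frames), standard well geometry (radius 7.75 mm for 24-well, 3.2 mm for
#' 96-well), measured larval body lengths (3.56 mm in 24-well, 3.85 mm in
#' 96-well), a typical array-microscope pixel scale of 37.8 um/px, and
#' keypoint-placement noise with marginal SD equal to the reported tracking
#' accuracy per plate format (0.0696 mm for 24-well, 0.1331 mm for 96-well),
#' temporally smoothed (AR(1), rho = 0.995) because tracking error is highly
#' correlated between consecutive frames.
#'
#' @param fps frames per second; default 160.
#' @param seconds acquisition length; default 10.
#' @param plate_format 24 or 96.
#' @param well_radius mm; default by plate format.
#' @param body_length mm; default by plate format.
#' @param pixel_size um per pixel; default 37.8.
#' @param noise_sd_mm marginal SD of keypoint jitter, mm; default by plate
#'   format.
#' @param noise_rho AR(1) temporal correlation of the jitter; default 0.995.
#' @return object of class \code{synthetic_config}.
#' @export
synthetic_config <- function(fps = 160, seconds = 10, plate_format = 24,
                             well_radius = NULL, body_length = NULL,
                             pixel_size = 37.8, noise_sd_mm = NULL,
                             noise_rho = 0.995) {
  if (!plate_format %in% c(24, 96))
    stop("plate_format must be 24 or 96")
  if (is.null(well_radius))
    well_radius <- if (plate_format == 24) 7.75 else 3.2
  if (is.null(body_length))
    body_length <- if (plate_format == 24) 3.56 else 3.85
  if (is.null(noise_sd_mm))
    noise_sd_mm <- if (plate_format == 24) 0.0696 else 0.1331
  stopifnot(fps > 0, seconds > 0, well_radius > body_length / 2,
            noise_sd_mm >= 0)
  structure(list(fps = fps, seconds = seconds, plate_format = plate_format,
                 well_radius = well_radius, body_length = body_length,
                 pixel_size = pixel_size, noise_sd_mm = noise_sd_mm,
                 noise_rho = noise_rho),
            class = "synthetic_config")
}

#' Keypoints of a bent fish body
#'
#' Lays the 8 keypoints along a polyline of total length
#' \code{config$body_length}: keypoint 1 (snout) at the head end, equal
#' segment lengths, segment directions turning by the 7 inter-keypoint bend
#' angles tailward. Zero curvature gives collinear points along the heading
#' with the snout in front. Cumulative bends beyond 300 degrees would
#' self-intersect severely; they are scaled down to 300 and the result is
#' flagged with attribute \code{clamped = TRUE}.
#'
#' @param position (x, y) of the body-center keypoint (keypoint 4), mm.
#' @param heading heading direction in degrees (+x = 0, CCW positive).
#' @param bend 7 signed inter-segment bend angles, degrees (positive bends
#'   the tail toward CCW).
#' @param config a [synthetic_config()] (only \code{body_length} is used).
#' @return 8 x 2 matrix of keypoint coordinates in mm.
#' @export
body_pose <- function(position, heading, bend, config) {
  stopifnot(length(bend) == 7)
  cumbend <- cumsum(bend)
  clamped <- FALSE
  if (max(abs(cumbend)) > 300) {
    bend <- bend * 300 / max(abs(cumbend))
    cumbend <- cumsum(bend)
    clamped <- TRUE
  }
  seg <- config$body_length / 7
  tailward <- (heading + 180 + cumbend) * pi / 180
  steps <- seg * exp(1i * tailward)
  z <- c(0, cumsum(steps))                 # snout at 0, tailward
  z <- z - z[4] + complex(real = position[1], imaginary = position[2])
  out <- cbind(Re(z), Im(z))
  attr(out, "clamped") <- clamped
  out
}

## Sample one realization of an archetype's bout profile (turn direction is
## chosen later, at bout onset, from the fish's position in the well).
## Returns list(d, speed, dh_abs, beat): per-frame speed, unsigned
## heading-change profile, and the sign-independent tail-beat component.
.bout_profile <- function(arch, fps) {
  d <- round(stats::runif(1, arch$duration_range[1], arch$duration_range[2]))
  v <- stats::runif(1, arch$peak_speed_range[1], arch$peak_speed_range[2])
  h <- stats::runif(1, arch$dheading_range[1], arch$dheading_range[2])
  ttp <- round(stats::runif(1, arch$time_to_peak_range[1],
                            min(arch$time_to_peak_range[2], d)))
  ttp <- max(1, min(ttp, d))
  i <- seq_len(d)
  speed <- v * sin(pi * i / (d + 1))                     # half-sine envelope
  cumh <- h * (1 - cos(pi * pmin(i, ttp) / ttp)) / 2     # s-curve to total h
  dh_abs <- diff(c(0, cumh))
  env <- sin(pi * i / (d + 1))
  beat <- arch$tail_amp * env * sin(2 * pi * 20 * i / fps)  # ~20 Hz tail beat
  list(d = d, speed = speed, dh_abs = dh_abs, beat = beat)
}

## Turn direction at bout onset: larvae in the outer well turn away from the
## wall (escape responses orient inward), otherwise the sign is random.
.turn_sign <- function(pos, heading, hmag, well_radius) {
  if (Mod(pos) < 0.4 * well_radius || hmag == 0)
    return(sample(c(-1, 1), 1))
  inward <- Arg(-pos) * 180 / pi
  d_plus <- abs(.wrap180(heading + hmag - inward))
  d_minus <- abs(.wrap180(heading - hmag - inward))
  if (d_plus < d_minus) 1 else if (d_minus < d_plus) -1 else sample(c(-1, 1), 1)
}

## distribute a total tail bend over the 7 joints, weighted caudally
.bend_weights <- (1:7) / sum(1:7)

#' Generate a synthetic pose track with ground-truth labels
#'
#' Simulates one fish in one well: frames outside scheduled bouts are
#' stationary (position and heading frozen; only tracking jitter moves the
#' keypoints), scheduled bouts follow their archetype's sampled speed,
#' heading-change and tail-bend profiles, and heading reflects specularly off
#' the well wall. Keypoint jitter is AR(1)-correlated Gaussian noise with
#' marginal SD \code{config$noise_sd_mm}. Deterministic given \code{seed}.
#'
#' @param schedule either the string \code{"random"} (spontaneous-like bout
#'   traffic, on average about one bout per second with spontaneous class
#'   frequencies), or a data.frame with columns \code{start_s} and
#'   \code{label} (archetype labels; non-overlapping, inside the
#'   acquisition).
#' @param config a [synthetic_config()].
#' @param seed RNG seed.
#' @param events optional list of [stimulus_event()] attached to the track.
#' @param noise_sd_mm override of the config's noise SD (e.g. 0 for
#'   noise-free ground truth).
#' @return list with \code{track} (a [pose_track()], coordinates in pixels)
#'   and \code{labels} (character, per-frame ground truth).
#' @export
generate_track <- function(schedule, config, seed = 1, events = list(),
                           noise_sd_mm = NULL) {
  set.seed(seed)
  fps <- config$fps
  T_ <- round(config$seconds * fps)
  if (is.null(noise_sd_mm)) noise_sd_mm <- config$noise_sd_mm

  if (identical(schedule, "random")) {
    schedule <- .random_schedule(config)
  }
  schedule <- as.data.frame(schedule)
  if (nrow(schedule)) {
    schedule <- schedule[order(schedule$start_s), , drop = FALSE]
    starts <- round(schedule$start_s * fps)
    if (any(starts < 0) || any(starts >= T_))
      stop("schedule error: bout outside the acquisition")
  }

  # sample bout realizations and check for overlap
  bouts <- list()
  if (nrow(schedule)) {
    for (i in seq_len(nrow(schedule))) {
      arch <- archetype_params(schedule$label[i], fps = fps)
      pr <- .bout_profile(arch, fps)
      s0 <- round(schedule$start_s[i] * fps)        # 0-based start frame
      pr$start <- s0
      pr$end <- min(s0 + pr$d, T_)                  # half-open
      pr$label <- schedule$label[i]
      bouts[[i]] <- pr
    }
    for (i in seq_len(length(bouts) - 1L))
      if (length(bouts) > 1 && bouts[[i]]$end > bouts[[i + 1L]]$start)
        stop("schedule error: overlapping bouts at ",
             schedule$start_s[i], " s and ", schedule$start_s[i + 1], " s")
  }

  # state trajectories
  margin <- config$body_length * 0.6
  r0 <- stats::runif(1, 0, max(config$well_radius - margin - 0.5, 0.1))
  th0 <- stats::runif(1, 0, 2 * pi)
  pos <- complex(real = r0 * cos(th0), imaginary = r0 * sin(th0))
  heading <- stats::runif(1, 0, 360)

  labels <- rep("stationary", T_)
  pos_tr <- complex(real = numeric(T_))
  head_tr <- numeric(T_)
  bend_tr <- numeric(T_)

  frame <- 1L
  for (b in bouts) {
    if (b$start + 1L > frame) {
      idx <- frame:(b$start)
      pos_tr[idx] <- pos; head_tr[idx] <- heading; bend_tr[idx] <- 0
      frame <- b$start + 1L
    }
    sgn <- .turn_sign(pos, heading, sum(b$dh_abs), config$well_radius)
    dheading <- sgn * b$dh_abs
    bend_total <- b$beat + pmax(pmin(2 * dheading, 120), -120)
    for (j in seq_len(b$end - b$start)) {
      heading <- heading + dheading[j]
      step <- (b$speed[j] / fps) * exp(1i * heading * pi / 180)
      nxt <- pos + step
      if (Mod(nxt) > config$well_radius - margin) {
        # specular reflection of heading about the wall normal at pos
        nrm <- Arg(pos) * 180 / pi
        heading <- .wrap180(2 * nrm + 180 - heading)
        step <- (b$speed[j] / fps) * exp(1i * heading * pi / 180)
        nxt <- pos + step
        if (Mod(nxt) > config$well_radius - margin) nxt <- pos
      }
      pos <- nxt
      pos_tr[frame] <- pos
      head_tr[frame] <- heading
      bend_tr[frame] <- bend_total[j]
      labels[frame] <- b$label
      frame <- frame + 1L
    }
  }
  if (frame <= T_) {
    idx <- frame:T_
    pos_tr[idx] <- pos; head_tr[idx] <- heading; bend_tr[idx] <- 0
  }

  # build keypoints (mm)
  co <- array(NA_real_, c(T_, 8, 2))
  same_as_prev <- c(FALSE, pos_tr[-1] == pos_tr[-T_] &
                             head_tr[-1] == head_tr[-T_] &
                             bend_tr[-1] == bend_tr[-T_])
  for (t in seq_len(T_)) {
    if (same_as_prev[t]) { co[t, , ] <- co[t - 1L, , ]; next }
    co[t, , ] <- body_pose(c(Re(pos_tr[t]), Im(pos_tr[t])), head_tr[t],
                           bend_tr[t] * .bend_weights, config)
  }

  if (noise_sd_mm > 0) {
    rho <- config$noise_rho
    innov_sd <- noise_sd_mm * sqrt(1 - rho^2)
    for (k in 1:8) for (d in 1:2) {
      e <- stats::rnorm(T_, 0, innov_sd)
      e[1] <- stats::rnorm(1, 0, noise_sd_mm)
      co[, k, d] <- co[, k, d] + stats::filter(e, rho, method = "recursive")
    }
  }

  px <- co * 1000 / config$pixel_size
  track <- pose_track(px, fps = fps, pixel_size = config$pixel_size,
                      plate_format = config$plate_format,
                      body_length = config$body_length, events = events)
  list(track = track, labels = labels)
}

## spontaneous-like random schedule: ~1 movement bout per second with the
## spontaneous class mix (scoot-heavy, startle-like rare)
.random_schedule <- function(config) {
  labs <- c("scoot", "turn", "AsLB", "VsLB")
  prob <- c(0.61, 0.28, 0.055, 0.055)
  t <- stats::runif(1, 0, 0.5)
  out <- list()
  while (t < config$seconds - 0.3) {
    lab <- sample(labs, 1, prob = prob)
    out[[length(out) + 1L]] <- data.frame(start_s = t, label = lab)
    t <- t + 0.3 + stats::rexp(1, rate = 1 / 0.7)  # bout + gap
  }
  if (!length(out)) return(data.frame(start_s = numeric(), label = character()))
  do.call(rbind, out)
}

#' Generate a balanced labeled window dataset
#'
#' Stands in for a manually reviewed clip library: for each class of the
#' plate format's class set, simulates short tracks containing one archetypal
#' bout (or pure stationary noise), windows and egocentrically aligns them,
#' and returns the aligned windows with their class labels. Each bout sits at
#' a random phase of its window (fully contained), as clips sampled from a
#' sliding window do — a classifier must recognize a bout wherever it falls
#' inside the 250 ms window for downstream majority voting to work. For the
#' 96-well format the merged "movement" class is realized as an even mix of
#' scoot and turn kinematics.
#'
#' @param config a [synthetic_config()].
#' @param n_per_class examples per class; >= 1.
#' @param seed RNG seed.
#' @param W window width; default 40.
#' @return list with \code{windows} (aligned \code{behavior_windows},
#'   n_classes * n_per_class of them) and \code{labels} (character).
#' @export
generate_labeled_dataset <- function(config, n_per_class, seed = 1, W = 40) {
  stopifnot(n_per_class >= 1)
  classes <- class_set(config$plate_format)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, length(classes) * n_per_class)
  s0 <- W + 5L                               # bout start frame in short track
  T_short <- s0 + 2L * W + 5L
  short <- synthetic_config(fps = config$fps,
                            seconds = T_short / config$fps,
                            plate_format = config$plate_format,
                            well_radius = config$well_radius,
                            body_length = config$body_length,
                            pixel_size = config$pixel_size,
                            noise_sd_mm = config$noise_sd_mm,
                            noise_rho = config$noise_rho)
  n_tot <- length(classes) * n_per_class
  co <- array(NA_real_, c(n_tot, W, 8, 2))
  labels <- character(n_tot)
  i <- 0L
  for (cl in classes) {
    for (j in seq_len(n_per_class)) {
      i <- i + 1L
      arch_label <- cl
      if (cl == "movement")
        arch_label <- if (j %% 2 == 0) "scoot" else "turn"
      sched <- if (arch_label == "stationary")
        data.frame(start_s = numeric(), label = character())
      else data.frame(start_s = s0 / config$fps, label = arch_label)
      g <- generate_track(sched, short, seed = seeds[i])
      w <- make_windows(g$track, W = W)
      # pick a window containing the whole bout at a random phase
      if (arch_label == "stationary") {
        wstart <- sample.int(T_short - W, 1) - 1L
      } else {
        d <- sum(g$labels != "stationary")
        wstart <- sample(max(0L, s0 + d - W):s0, 1)
      }
      one <- structure(list(coords = w$coords[wstart + 1L, , , ,
                                              drop = FALSE],
                            starts = wstart, usable = w$usable[wstart + 1L],
                            aligned = FALSE, W = W, fps = w$fps,
                            pixel_size = w$pixel_size,
                            plate_format = w$plate_format),
                       class = "behavior_windows")
      co[i, , , ] <- egocentric_align(one)$coords[1, , , ]
      labels[i] <- cl
    }
  }
  windows <- structure(list(coords = co, starts = rep(0L, n_tot),
                            usable = rep(TRUE, n_tot), aligned = TRUE,
                            W = W, fps = config$fps,
                            pixel_size = config$pixel_size,
                            plate_format = config$plate_format),
                       class = "behavior_windows")
  list(windows = windows, labels = labels)
}
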