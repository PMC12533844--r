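# Fixtures are built in code; no files are shipped.

# A rigid fish body: 8 collinear keypoints of total length `len_px` pixels,
# head at `head`, pointing along `heading` degrees (internal Cartesian).
straight_pose <- function(head = c(0, 0), heading = 0, len_px = 80) {
  u <- c(cos(heading * pi / 180), sin(heading * pi / 180))
  t(vapply(0:7, function(i) head - i * (len_px / 7) * u, numeric(2)))
}

# Track whose center keypoint translates by `step_px` per frame along
# `heading`, body rigid and straight.
straight_track <- function(T = 50, step_px = 1, heading = 0, fps = 160,
                           pixel_size = 100, len_px = 80) {
  u <- c(cos(heading * pi / 180), sin(heading * pi / 180))
  co <- array(NA_real_, c(T, 8, 2))
  base <- straight_pose(c(0, 0), heading, len_px)
  for (t in seq_len(T))
    co[t, , ] <- base + rep((t - 1) * step_px * u, each = 8)
  pose_track(co, fps = fps, pixel_size = pixel_size)
}

# Track rotating rigidly about its center by `deg_per_frame`.
rotating_track <- function(T = 50, deg_per_frame = 5, fps = 160,
                           pixel_size = 100, len_px = 80) {
  co <- array(NA_real_, c(T, 8, 2))
  for (t in seq_len(T))
    co[t, , ] <- straight_pose(c(0, 0), (t - 1) * deg_per_frame, len_px)
  pose_track(co, fps = fps, pixel_size = pixel_size)
}

# Apply a rigid motion (rotation `deg` about the origin then translation) to
# every frame of a window coordinate array.
rigid_motion <- function(co, deg, shift) {
  d3 <- dim(co)[1:3]
  z <- array(co[, , , 1, drop = FALSE], d3) +
    1i * array(co[, , , 2, drop = FALSE], d3)
  z <- z * exp(1i * deg * pi / 180) + complex(real = shift[1],
                                              imaginary = shift[2])
  out <- co
  out[, , , 1] <- Re(z)
  out[, , , 2] <- Im(z)
  out
}

# Independent brute-force majority-vote oracle (per-frame loop, explicit
# candidate enumeration).
oracle_vote <- function(window_labels, W, T, classes) {
  n <- length(window_labels)
  out <- character(T)
  for (t in 0:(T - 1)) {
    cand <- window_labels[seq_len(n) - 1 >= t - W + 1 &
                          seq_len(n) - 1 <= t]
    cand <- cand[cand %in% classes]
    if (!length(cand)) { out[t + 1] <- "unknown"; next }
    counts <- vapply(classes, function(cl) sum(cand == cl), numeric(1))
    out[t + 1] <- classes[which.max(counts)]
  }
  out
}

# Small labeled dataset + classifier, shared across classifier tests.
tiny_trained <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- synthetic_config(plate_format = 24)
      ds <- generate_labeled_dataset(cfg, 25, seed = 42)
      fe <- featurize(ds$windows)
      sp <- split_dataset(ds$labels, 0.9, seed = 1)
      tr <- fe
      tr$vectors <- fe$vectors[sp$train, , drop = FALSE]
      tr$usable <- fe$usable[sp$train]
      tr$window_starts <- fe$window_starts[sp$train]
      te <- fe
      te$vectors <- fe$vectors[sp$test, , drop = FALSE]
      te$usable <- fe$usable[sp$test]
      te$window_starts <- fe$window_starts[sp$test]
      cache <<- list(cfg = cfg, ds = ds, features = fe, split = sp,
                     train = tr, test = te,
                     clf = train_classifier(tr, ds$labels[sp$train],
                                            rf_seed = 7, ntree = 50))
    }
    cache
  }
})
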