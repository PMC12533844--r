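test_that("windowing yields T - W windows with the stated starts", {
  g <- generate_track("random", synthetic_config(plate_format = 24), seed = 2)
  w <- make_windows(g$track)                   # T = 1600, W = 40
  expect_equal(length(w$starts), 1560L)
  expect_equal(w$starts, 0:1559)

  t41 <- straight_track(T = 41)
  w41 <- make_windows(t41, W = 40)
  expect_equal(length(w41$starts), 1L)
  expect_equal(w41$starts, 0L)

  t100 <- straight_track(T = 100)
  w100 <- make_windows(t100, W = 10)
  expect_equal(length(w100$starts), 90L)
  expect_equal(w100$starts, 0:89)

  expect_error(make_windows(straight_track(T = 40), W = 40), "41")
})

test_that("windows slice the track faithfully and flag masked frames", {
  tr <- straight_track(T = 30, step_px = 3)
  tr$missing[12, 5] <- TRUE
  w <- make_windows(tr, W = 10)
  for (i in c(1, 7, 20))
    expect_equal(w$coords[i, , , ], tr$coords[i:(i + 9), , ])
  # windows overlapping frame 12 (start 3..12 in 1-based = starts 2..11) unusable
  expect_false(any(w$usable[3:12]))
  expect_true(all(w$usable[-(3:12)]))
})

test_that("egocentric alignment puts frame 0 in canonical pose exactly", {
  g <- generate_track("random", synthetic_config(plate_format = 24,
                                                 seconds = 1), seed = 5)
  w <- egocentric_align(make_windows(g$track))
  n <- length(w$starts)
  expect_equal(max(abs(w$coords[, 1, 4, ])), 0, tolerance = 1e-9)  # center at origin
  expect_equal(max(abs(w$coords[, 1, 1, 1])), 0, tolerance = 1e-9) # snout x = 0
  expect_true(all(w$coords[, 1, 1, 2] > 0))                        # snout on +y
})

test_that("a worked alignment example: heading +x becomes +y", {
  co <- array(0, c(1, 2, 8, 2))
  co[1, 1, , 1] <- c(6, 5.8, 5.6, 5, 4.8, 4.6, 4.4, 4.2)  # snout x=6, center x=5
  co[1, 1, , 2] <- 5
  co[1, 2, , ] <- co[1, 1, , ]
  w <- structure(list(coords = co, starts = 0L, usable = TRUE,
                      aligned = FALSE, W = 2L, fps = 160, pixel_size = 100,
                      plate_format = 24),
                 class = "behavior_windows")
  a <- egocentric_align(w)
  expect_equal(a$coords[1, 1, 4, ], c(0, 0), tolerance = 1e-12)
  expect_equal(a$coords[1, 1, 1, ], c(0, 1), tolerance = 1e-12)
})

test_that("alignment is idempotent, rigid-motion invariant, distance-preserving", {
  g <- generate_track(data.frame(start_s = 0.2, label = "AsLB"),
                      synthetic_config(plate_format = 24, seconds = 0.6),
                      seed = 10)
  w <- make_windows(g$track, W = 20)
  a1 <- egocentric_align(w)
  # idempotence
  a2 <- egocentric_align(a1)
  expect_identical(a1$coords, a2$coords)

  # pairwise intra-frame distances preserved
  pd <- function(co, i, t) as.vector(dist(co[i, t, , ]))
  for (t in c(1, 10, 20))
    expect_equal(pd(a1$coords, 3, t), pd(w$coords, 3, t), tolerance = 1e-9)

  # invariance to 50 random rigid motions of the input
  set.seed(77)
  body_px <- 3.56 * 1000 / g$track$pixel_size
  for (rep in 1:50) {
    moved <- w
    moved$coords <- rigid_motion(w$coords, runif(1, -180, 180),
                                 runif(2, -500, 500))
    am <- egocentric_align(moved)
    expect_equal(am$coords, a1$coords, tolerance = 1e-6 * body_px)
  }
})

test_that("degenerate frame-0 pose is refused, not silently aligned", {
  co <- array(1, c(1, 3, 8, 2))    # every keypoint identical
  w <- structure(list(coords = co, starts = 0L, usable = TRUE,
                      aligned = FALSE, W = 3L, fps = 160, pixel_size = 100,
                      plate_format = 24),
                 class = "behavior_windows")
  expect_warning(a <- egocentric_align(w), "coincident")
  expect_false(a$usable[1])
})

test_that("featurize flattens to W*16 values and normalizes with two scalars", {
  ds <- generate_labeled_dataset(synthetic_config(plate_format = 24), 3,
                                 seed = 6)
  fm <- featurize(ds$windows)
  expect_equal(ncol(fm$vectors), 640L)

  # independent elementwise oracle: v / max - mean, in flattening order
  co <- ds$windows$coords
  n <- dim(co)[1]
  flat <- matrix(NA_real_, n, 640)
  for (i in seq_len(n)) {
    v <- numeric(0)
    for (t in 1:40) for (k in 1:8) v <- c(v, co[i, t, k, 1], co[i, t, k, 2])
    flat[i, ] <- v
  }
  mx <- max(abs(flat))
  mn <- mean(flat / mx)
  expect_equal(fm$norm_max, mx)
  expect_equal(fm$norm_mean, mn)
  expect_equal(fm$vectors, flat / mx - mn, tolerance = 1e-12)

  # frozen stats reproduce training-time scaling on new data
  fm2 <- featurize(ds$windows, stats = list(norm_max = 2 * mx, norm_mean = 0.1))
  expect_equal(fm2$vectors, flat / (2 * mx) - 0.1, tolerance = 1e-12)
  expect_error(featurize(ds$windows, stats = list(norm_max = 0,
                                                  norm_mean = 0)), "norm_max")
})

test_that("flatten then unflatten is the identity on window arrays", {
  set.seed(9)
  co <- array(rnorm(5 * 12 * 8 * 2), c(5, 12, 8, 2))
  w <- structure(list(coords = co, starts = 0:4, usable = rep(TRUE, 5),
                      aligned = TRUE, W = 12L, fps = 160, pixel_size = 100,
                      plate_format = 24),
                 class = "behavior_windows")
  fm <- featurize(w, stats = list(norm_max = 1, norm_mean = 0))
  expect_equal(unflatten_windows(fm$vectors, W = 12), co, tolerance = 1e-12)
})

test_that("unaligned windows cannot be featurized", {
  tr <- straight_track(T = 15)
  expect_error(featurize(make_windows(tr, W = 10)), "aligned")
})
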