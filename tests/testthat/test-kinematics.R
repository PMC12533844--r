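test_that("closed forms: speed, heading change, tail angle", {
  # 1 px/frame at 100 um/px, 160 fps -> 0.1 mm * 160 = 16 mm/s
  tr <- straight_track(T = 20, step_px = 1, pixel_size = 100, fps = 160)
  k <- kinematic_series(tr)
  expect_equal(k$speed[-1], rep(16, 19), tolerance = 1e-9)
  expect_equal(k$speed[1], 0)
  expect_equal(k$dheading, rep(0, 20), tolerance = 1e-9)
  expect_equal(k$tail_angle, rep(0, 20), tolerance = 1e-9)   # straight body

  # rigid rotation: heading change equals the applied per-frame angle
  rot <- rotating_track(T = 30, deg_per_frame = 7)
  kr <- kinematic_series(rot)
  expect_equal(kr$dheading[-1], rep(7, 29), tolerance = 1e-9)
  # a 90-degree jump between two frames
  co <- array(NA_real_, c(2, 8, 2))
  co[1, , ] <- straight_pose(c(0, 0), 0)
  co[2, , ] <- straight_pose(c(0, 0), 90)
  k90 <- kinematic_series(pose_track(co, 160, 100))
  expect_equal(k90$dheading[2], 90, tolerance = 1e-9)
})

test_that("heading winds by 360 degrees per lap of a circular swim", {
  T_ <- 73
  co <- array(NA_real_, c(T_, 8, 2))
  for (t in seq_len(T_)) {
    ang <- (t - 1) * 5                      # 72 steps of 5 deg = one lap
    ctr <- 200 * c(cos(ang * pi / 180), sin(ang * pi / 180))
    co[t, , ] <- straight_pose(ctr, ang + 90)  # tangent heading
  }
  k <- kinematic_series(pose_track(co, 160, 100))
  expect_equal(sum(k$dheading), 360, tolerance = 1e-6)
})

test_that("speed is invariant to global rigid motion of the track", {
  g <- generate_track(data.frame(start_s = 0.1, label = "scoot"),
                      synthetic_config(plate_format = 24, seconds = 0.5),
                      seed = 12)
  k1 <- kinematic_series(g$track)
  co4 <- array(g$track$coords, c(dim(g$track$coords)[1], 1, 8, 2))
  co4 <- aperm(co4, c(2, 1, 3, 4))
  moved <- rigid_motion(co4, 123, c(40, -60))
  tr2 <- pose_track(array(moved[1, , , ], dim(g$track$coords)),
                    g$track$fps, g$track$pixel_size)
  k2 <- kinematic_series(tr2)
  expect_equal(k2$speed, k1$speed, tolerance = 1e-9)
  expect_equal(k2$dheading, k1$dheading, tolerance = 1e-8)
  expect_equal(k2$tail_angle, k1$tail_angle, tolerance = 1e-8)
})

test_that("speed bouts follow the threshold/min-length rule exactly", {
  expect_equal(detect_speed_bouts(c(0, 3, 3, 3, 3, 3, 0), 2, 5),
               data.frame(start_frame = 1L, end_frame = 6L))
  expect_equal(nrow(detect_speed_bouts(c(0, 3, 3, 3, 0), 2, 5)), 0L)
  expect_equal(nrow(detect_speed_bouts(rep(1, 50), 2, 5)), 0L)
  # threshold is strict
  expect_equal(nrow(detect_speed_bouts(rep(2, 50), 2, 5)), 0L)
})

test_that("speed-bout detection matches a brute-force scan on random series", {
  set.seed(31)
  for (rep in 1:40) {
    sp <- round(runif(60, 0, 5), 1)
    got <- detect_speed_bouts(sp, 2, 5)
    # oracle: explicit scan for maximal runs
    above <- sp > 2
    runs <- list()
    t <- 1
    while (t <= 60) {
      if (above[t]) {
        s <- t
        while (t <= 60 && above[t]) t <- t + 1
        if (t - s >= 5) runs[[length(runs) + 1]] <- c(s - 1, t - 1)
      } else t <- t + 1
    }
    expect_equal(nrow(got), length(runs))
    for (i in seq_along(runs)) {
      expect_equal(got$start_frame[i], runs[[i]][1])
      expect_equal(got$end_frame[i], runs[[i]][2])
    }
    # disjoint and maximal
    if (nrow(got) > 1)
      expect_true(all(got$start_frame[-1] > got$end_frame[-nrow(got)]))
  }
})

test_that("interval maxima behave as max |x| and grow with the interval", {
  expect_equal(interval_max(c(1, -3, 2), data.frame(start_frame = 0,
                                                    end_frame = 3)), 3)
  expect_equal(interval_max(c(1, -3, 2), data.frame(start_frame = 0,
                                                    end_frame = 3),
                            signed = TRUE), 2)
  expect_equal(interval_max(rep(0, 10), data.frame(start_frame = 2,
                                                   end_frame = 8)), 0)
  expect_error(interval_max(1:5, data.frame(start_frame = 2, end_frame = 2)),
               "empty")
  set.seed(17)
  x <- rnorm(100)
  for (rep in 1:20) {
    a <- sample(0:50, 1); b <- a + sample(1:40, 1)
    wide <- c(max(a - sample(0:a, 1), 0), min(b + sample(0:10, 1), 100))
    expect_gte(interval_max(x, list(wide)), interval_max(x, list(c(a, b))))
  }
})

test_that("annotate_bouts summarizes each bout over its own frames", {
  tr <- straight_track(T = 20, step_px = 1, pixel_size = 100, fps = 160)
  k <- kinematic_series(tr)
  b <- data.frame(label = "scoot", start_frame = 4, end_frame = 10)
  ab <- annotate_bouts(b, k)
  expect_equal(ab$duration_ms, 6 / 160 * 1000)   # 37.5 ms
  expect_equal(ab$max_speed_mm_s, 16, tolerance = 1e-9)
  expect_equal(ab$max_abs_dheading_deg, 0, tolerance = 1e-9)
  # synthetic AsLB: annotated heading change consistent with the archetype
  g <- generate_track(data.frame(start_s = 0.3, label = "AsLB"),
                      synthetic_config(plate_format = 24, seconds = 1,
                                       well_radius = 30),
                      seed = 5, noise_sd_mm = 0)
  kg <- kinematic_series(g$track)
  idx <- which(g$labels == "AsLB") - 1
  bg <- annotate_bouts(data.frame(label = "AsLB", start_frame = min(idx),
                                  end_frame = max(idx) + 1), kg)
  a <- archetype_params("AsLB")
  expect_gte(bg$max_speed_mm_s, a$peak_speed_range[1] * 0.8)
  expect_lte(bg$max_speed_mm_s, a$peak_speed_range[2] * 1.05)
  expect_gt(bg$max_abs_dheading_deg, 15)   # fast turn: large per-frame change
})
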