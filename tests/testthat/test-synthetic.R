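cfg24 <- synthetic_config(plate_format = 24)

test_that("body_pose lays a straight body along the heading", {
  p <- body_pose(c(0, 0), 90, rep(0, 7), cfg24)
  # collinear along +y, snout (keypoint 1) at the head end
  expect_equal(p[, 1], rep(0, 8), tolerance = 1e-12)
  expect_true(all(diff(p[, 2]) < 0))          # tailward is -y
  expect_equal(p[1, 2] - p[8, 2], cfg24$body_length, tolerance = 1e-12)
  expect_equal(p[4, ], c(0, 0), tolerance = 1e-12)   # center at position
  expect_false(attr(p, "clamped"))
  # severe curvature is clamped and flagged
  p2 <- body_pose(c(0, 0), 0, rep(360 / 7, 7), cfg24)
  expect_true(attr(p2, "clamped"))
})

test_that("generate_track is deterministic and honors the schedule", {
  sched <- data.frame(start_s = 2.0, label = "scoot")
  g1 <- generate_track(sched, cfg24, seed = 99)
  g2 <- generate_track(sched, cfg24, seed = 99)
  expect_identical(g1$track$coords, g2$track$coords)
  expect_identical(g1$labels, g2$labels)
  r <- rle(g1$labels)
  expect_equal(sum(r$values == "scoot"), 1L)
  expect_equal(which(g1$labels == "scoot")[1] - 1L, 320L)  # 2.0 s x 160 fps
  expect_error(generate_track(data.frame(start_s = c(2, 2.01),
                                         label = c("scoot", "scoot")),
                              cfg24, seed = 1), "overlap")
})

test_that("generated bodies are rigid at zero noise", {
  g <- generate_track(data.frame(start_s = c(0.5, 2), label = c("AsLB", "scoot")),
                      synthetic_config(plate_format = 24, seconds = 3),
                      seed = 4, noise_sd_mm = 0)
  co <- g$track$coords * cfg24$pixel_size / 1000   # px -> mm
  seg <- cfg24$body_length / 7
  d <- sqrt(apply((co[, -1, ] - co[, -8, ])^2, c(1, 2), sum))
  expect_equal(as.vector(d), rep(seg, length(d)), tolerance = 1e-9)
})

test_that("stationary frames stay under the 2 mm/s threshold at zero noise", {
  g <- generate_track(data.frame(start_s = 1, label = "turn"),
                      synthetic_config(plate_format = 24, seconds = 3),
                      seed = 8, noise_sd_mm = 0)
  k <- kinematic_series(g$track)
  stat <- g$labels == "stationary"
  stat[1] <- FALSE                    # frame-0 pad
  # drop the frame following a bout end (displacement across the boundary)
  stat[which(c(FALSE, diff(stat) == 1))] <- FALSE
  expect_true(all(k$speed[stat] < 2))
})

test_that("archetype kinematics recomputed from tracks separate classes", {
  # derived check: simulate each archetype at zero noise, recompute max
  # speed / max |dheading| with the kinematics module, compare to parameters
  summaries <- lapply(c("scoot", "turn", "AsLB", "VsLB"), function(lab) {
    mx_h <- mx_v <- numeric(12)
    for (s in 1:12) {
      # large arena so wall reflections cannot contaminate the archetype
      g <- generate_track(data.frame(start_s = 0.5, label = lab),
                          synthetic_config(plate_format = 24, seconds = 1.5,
                                           well_radius = 30),
                          seed = s, noise_sd_mm = 0)
      k <- kinematic_series(g$track)
      idx <- which(g$labels == lab)
      tot_h <- abs(sum(k$dheading[idx]))
      mx_h[s] <- tot_h
      mx_v[s] <- max(k$speed[idx])
    }
    list(label = lab, heading = mx_h, speed = mx_v)
  })
  names(summaries) <- c("scoot", "turn", "AsLB", "VsLB")
  a <- archetype_params("AsLB")
  # AsLB total heading change within its configured range...
  expect_true(all(summaries$AsLB$heading >= a$dheading_range[1] - 1 &
                  summaries$AsLB$heading <= a$dheading_range[2] + 1))
  # ...and above the scoot range maximum (zero overlap at sigma = 0)
  expect_true(min(summaries$AsLB$heading) >
              max(archetype_params("scoot")$dheading_range))
  expect_true(min(summaries$AsLB$speed) > max(summaries$scoot$speed))
  expect_true(min(summaries$VsLB$heading) > max(summaries$scoot$heading))
  expect_true(min(summaries$turn$heading) > max(summaries$scoot$heading))
})

test_that("generate_labeled_dataset is balanced, plate-aware, deterministic", {
  d24 <- generate_labeled_dataset(cfg24, 10, seed = 1)
  expect_equal(length(d24$labels), 50L)
  expect_equal(sort(unique(d24$labels)), sort(class_set(24)))
  expect_true(all(table(d24$labels) == 10))
  expect_true(d24$windows$aligned)
  expect_equal(dim(d24$windows$coords), c(50L, 40L, 8L, 2L))

  cfg96 <- synthetic_config(plate_format = 96)
  d96 <- generate_labeled_dataset(cfg96, 10, seed = 1)
  expect_equal(length(d96$labels), 40L)
  expect_equal(sort(unique(d96$labels)),
               sort(c("stationary", "movement", "AsLB", "VsLB")))

  d24b <- generate_labeled_dataset(cfg24, 10, seed = 1)
  expect_identical(d24$windows$coords, d24b$windows$coords)
  expect_identical(d24$labels, d24b$labels)
})
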