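classesAB <- c("A", "B")

test_that("unanimous windows give unanimous frames with full-coverage margin", {
  T_ <- 30; W <- 10
  fl <- majority_vote(rep("scoot", T_ - W), W, T_, class_set(24))
  # the last frame is covered by no window under the T - W convention
  expect_true(all(fl$labels[-T_] == "scoot"))
  expect_equal(fl$labels[T_], "unknown")
  # margin equals the number of overlapping windows at each frame
  cover <- vapply(0:(T_ - 1), function(t)
    sum(0:(T_ - W - 1) >= t - W + 1 & 0:(T_ - W - 1) <= t), numeric(1))
  expect_equal(fl$margin, as.integer(cover))
})

test_that("a single deviant window never wins against a consistent run", {
  T_ <- 120; W <- 40
  wl <- rep("scoot", T_ - W)
  wl[40] <- "turn"
  fl <- majority_vote(wl, W, T_, class_set(24))
  expect_true(all(fl$labels[-T_] == "scoot"))
})

test_that("the worked two-block example votes as enumerated", {
  # windows 0-9 labeled A, 10-39 labeled B; frame 15's candidates are starts
  # 6..15: four A, six B -> B
  T_ <- 50; W <- 10
  wl <- c(rep("A", 10), rep("B", 30))
  fl <- majority_vote(wl, W, T_, classesAB)
  expect_equal(fl$labels[16], "B")
  expect_equal(fl$margin[16], 2L)            # 6 - 4
  expect_equal(fl$labels, oracle_vote(wl, W, T_, classesAB))
})

test_that("voting agrees with the brute-force oracle on random sequences", {
  set.seed(123)
  for (rep in 1:60) {
    W <- sample(3:12, 1)
    T_ <- W + sample(5:40, 1)
    cls <- c("stationary", "scoot", "turn")
    wl <- sample(c(cls, "unknown"), T_ - W, replace = TRUE)
    fl <- majority_vote(wl, W, T_, cls)
    expect_identical(fl$labels, oracle_vote(wl, W, T_, cls))
  }
})

test_that("a >50% label always wins and labels are never invented", {
  set.seed(321)
  for (rep in 1:30) {
    W <- 8; T_ <- 40
    cls <- c("stationary", "scoot", "turn", "AsLB")
    wl <- sample(cls, T_ - W, replace = TRUE, prob = c(5, 2, 1, 1))
    fl <- majority_vote(wl, W, T_, cls)
    for (t in 0:(T_ - 1)) {
      cand <- wl[0:(T_ - W - 1) >= t - W + 1 & 0:(T_ - W - 1) <= t]
      if (!length(cand)) {
        expect_equal(fl$labels[t + 1], "unknown")
        next
      }
      maj <- names(which(table(cand) > length(cand) / 2))
      if (length(maj)) expect_equal(fl$labels[t + 1], maj)
      expect_true(fl$labels[t + 1] %in% cand)   # no invented labels
    }
  }
})

test_that("ties break toward the earlier class in the set order", {
  # frame 1 (0-based) of W=2: candidates are windows 0 and 1
  fl <- majority_vote(c("B", "A", "A"), 2, 5, classesAB)
  expect_equal(fl$labels[2], "A")    # 1 vs 1 -> earlier label A
  expect_equal(fl$margin[2], 0L)
})

test_that("frames with no usable window are unknown", {
  fl <- majority_vote(c("unknown", "unknown", "A"), 2, 5, classesAB)
  expect_equal(fl$labels[1], "unknown")
  expect_equal(fl$margin[1], 0L)
  expect_equal(fl$labels[4], "A")
})

test_that("bout extraction matches a run-length oracle (strict > min_run)", {
  set.seed(55)
  for (rep in 1:40) {
    labs <- sample(c("stationary", "scoot", "turn", "unknown"), 80,
                   replace = TRUE, prob = c(4, 3, 2, 1))
    labs <- rep(labs, times = sample(1:8, 80, replace = TRUE))[1:80]
    got <- extract_bouts(labs, min_run = 5)
    # independent oracle via rle
    r <- rle(labs)
    keep <- r$lengths > 5 & r$values != "unknown"
    expect_equal(nrow(got), sum(keep))
    if (nrow(got)) {
      ends <- cumsum(r$lengths)
      expect_equal(got$label, r$values[keep])
      expect_equal(got$start_frame, (ends - r$lengths)[keep])
      expect_equal(got$end_frame, ends[keep])
    }
  }
})

test_that("bout boundary rules are strict and durations exact", {
  labs <- c(rep("scoot", 10), rep("turn", 3), rep("scoot", 10))
  b <- extract_bouts(labs, min_run = 5, fps = 160)
  expect_equal(nrow(b), 2L)
  expect_true(all(b$label == "scoot"))

  b6 <- extract_bouts(rep("AsLB", 6), min_run = 5, fps = 160)
  expect_equal(nrow(b6), 1L)
  expect_equal(b6$duration_ms, 37.5)        # 6 frames / 160 fps

  expect_equal(nrow(extract_bouts(rep("turn", 5), min_run = 5)), 0L)
})

test_that("bouts plus gaps partition the acquisition", {
  fl <- majority_vote(sample(c("scoot", "turn"), 100, replace = TRUE,
                             prob = c(3, 1)), 10, 110, class_set(24))
  b <- extract_bouts(fl, min_run = 5)
  if (nrow(b) > 1) {
    expect_true(all(diff(b$start_frame) > 0))
    expect_true(all(b$end_frame[-nrow(b)] <= b$start_frame[-1]))
  }
  # every bout's frames carry its label
  for (i in seq_len(nrow(b)))
    expect_true(all(fl$labels[(b$start_frame[i] + 1):b$end_frame[i]] ==
                    b$label[i]))
})

test_that("interval filtering uses half-open overlap", {
  b <- data.frame(label = c("AsLB", "scoot", "turn"),
                  start_frame = c(790, 0, 700),
                  end_frame = c(820, 100, 800))
  kept <- filter_bouts_by_interval(b, c(800, 840))
  expect_equal(kept$label, "AsLB")           # [790,820) overlaps [800,840)
  # [700,800) touches but does not overlap; [0,100) disjoint
})
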