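test_that("uniform motion gives constant velocity and zero acceleration", {
  s <- make_stroke(c(0, 1000, 2000, 3000), c(0, 100, 200, 300), rep(0, 4))
  a <- derive_axis_series(s, default_device(), "x")
  expect_equal(a$position, c(0, 0.1, 0.2, 0.3))
  expect_equal(a$velocity, c(0.1, 0.1, 0.1))
  expect_equal(a$acceleration, c(0, 0))
})

test_that("a zigzag trace gives the hand-computed finite differences", {
  s <- make_stroke(c(0, 1000, 2000, 3000), c(0, 100, 0, 100), rep(0, 4))
  a <- derive_axis_series(s, default_device(), "x")
  expect_equal(a$velocity, c(0.1, -0.1, 0.1))
  expect_equal(a$acceleration, c(-0.2, 0.2))
  # the same zigzag as a session: 2 velocity reversals, 1 acceleration
  # reversal on x, identical per-line values for the single line
  ft <- extract_features(make_session(list(s)))
  expect_equal(ft$vel_sign_changes_x, 2)
  expect_equal(ft$acc_sign_changes_x, 1)
  expect_equal(ft$vel_sign_changes_x_per_line, 2)
  expect_equal(ft$acc_sign_changes_x_per_line, 1)
})

test_that("degenerate strokes yield empty derivative series", {
  dev <- default_device()
  one <- stroke(data.frame(t = 0, x = 1, y = 1, phase = "down"),
                truncated = TRUE)
  a <- derive_axis_series(one, dev, "x")
  expect_length(a$velocity, 0)
  expect_length(a$acceleration, 0)
  # all events at one timestamp collapse to a single point
  dup <- make_stroke(c(0, 0, 0), c(1, 2, 3), c(1, 1, 1))
  a2 <- derive_axis_series(dup, dev, "x")
  expect_length(a2$position, 1)
  expect_equal(a2$position, 3 / dev$width_px)  # last sample wins
  expect_length(a2$velocity, 0)
})

test_that("sign-change counting treats zeros as transparent", {
  expect_equal(count_sign_changes(c(0.1, 0.1, 0.1)), 0)
  expect_equal(count_sign_changes(c(0.1, -0.1, 0.1)), 2)
  expect_equal(count_sign_changes(c(0.1, 0, -0.1, 0, 0.1)), 2)
  expect_equal(count_sign_changes(c(0, 0, 0)), 0)
  expect_equal(count_sign_changes(numeric(0)), 0)
  # brute-force agreement over random signed series with many zeros
  set.seed(42)
  for (i in 1:50) {
    x <- sample(c(-2, -1, 0, 0, 1, 2), sample(1:20, 1), replace = TRUE)
    expect_equal(count_sign_changes(x), oracle_sign_changes(x))
  }
})

test_that("feature extraction matches hand-computed session summaries", {
  dev <- default_device()
  # one straight horizontal stroke spanning the full width
  s1 <- make_stroke(c(0, 1000, 2000), c(0, 500, 1000), c(400, 400, 400))
  ft1 <- extract_features(make_session(list(s1), dev))
  expect_equal(ft1$width_max_ratio, 1)
  expect_equal(ft1$height_mean_ratio, 0)
  expect_equal(ft1$height_max_ratio, 0)
  expect_equal(ft1$line_number, 1)
  expect_equal(ft1$vel_sign_changes_x + ft1$vel_sign_changes_y +
                 ft1$acc_sign_changes_x + ft1$acc_sign_changes_y, 0)
  # vertical extents 0.2 and 0.4 of the 800 px screen
  s2 <- make_stroke(c(0, 1000), c(0, 0), c(0, 160))
  s3 <- make_stroke(c(2000, 3000), c(0, 0), c(0, 320))
  ft2 <- extract_features(make_session(list(s2, s3), dev))
  expect_equal(ft2$height_mean_ratio, 0.3)
  expect_equal(ft2$height_max_ratio, 0.4)
})

test_that("an empty session gives all-zero features with a degenerate flag", {
  ft <- extract_features(make_session(list()))
  expect_true(ft$degenerate)
  expect_equal(ft$playtime_s, 0)
  expect_equal(ft$line_number, 0)
})

test_that("every feature equals the brute-force oracle on random strokes", {
  set.seed(7)
  for (i in 1:25) {
    s <- random_session(sample(1:5, 1))
    ft <- extract_features(s)
    or <- oracle_features(s)
    for (f in names(or)) expect_identical(ft[[f]], or[[f]])
  }
})

test_that("ratio features are invariant to uniform pixel rescaling", {
  set.seed(11)
  s <- random_session(3)
  scale_session <- function(s, k) {
    s$device <- device_info(s$device$width_px * k, s$device$height_px * k,
                            s$device$diagonal_in)
    s$strokes <- lapply(s$strokes, function(st) {
      st$events$x <- st$events$x * k
      st$events$y <- st$events$y * k
      st
    })
    s
  }
  f1 <- extract_features(s)
  f2 <- extract_features(scale_session(s, 2.5))
  for (f in setdiff(feature_names(), NULL))
    expect_equal(f2[[f]], f1[[f]], tolerance = 1e-12)
})

test_that("adding an oscillating stroke never lowers sign-change counts", {
  set.seed(13)
  dev <- default_device()
  for (i in 1:10) {
    s <- random_session(2, device = dev)
    t_end <- max(session_events(s)$t)
    n <- 30
    t <- t_end + 500 + seq(0, by = 33, length.out = n)
    zig <- make_stroke(t, 500 + 100 * sin(seq_len(n)), rep(400, n))
    s2 <- s; s2$strokes <- c(s$strokes, list(zig))
    f1 <- extract_features(s); f2 <- extract_features(s2)
    for (f in grep("sign_changes_[xy]$", feature_names(), value = TRUE))
      expect_gte(f2[[f]], f1[[f]])
  }
})

test_that("reversing stroke event order preserves sign-change counts", {
  set.seed(17)
  for (i in 1:10) {
    # uniform time grid (fixed logging rate): reversal then mirrors the
    # velocity sign sequence and reverses the acceleration sign sequence
    strokes <- lapply(1:3, function(k) {
      n <- sample(5:25, 1)
      make_stroke((k - 1) * 5000 + seq(0, by = 33, length.out = n),
                  cumsum(rnorm(n, 0, 30)) + 500,
                  cumsum(rnorm(n, 0, 30)) + 400)
    })
    s <- make_session(strokes)
    rev_session <- s
    rev_session$strokes <- lapply(s$strokes, function(st) {
      ev <- st$events[rev(seq_len(nrow(st$events))), ]
      ev$t <- st$events$t  # same time grid, path traversed backwards
      ev$phase <- st$events$phase
      rownames(ev) <- NULL
      stroke(ev)
    })
    f1 <- extract_features(s); f2 <- extract_features(rev_session)
    for (f in grep("sign_changes", feature_names(), value = TRUE))
      expect_equal(f2[[f]], f1[[f]])
  }
})

test_that("sequence input pads, truncates, and marks stroke boundaries", {
  dev <- default_device()
  s4 <- make_session(list(make_stroke(c(0, 33, 66, 100), 1:4 * 10, 1:4 * 10)),
                     dev)
  si <- build_sequence_input(s4, max_len = 8)
  expect_equal(si$n_valid, 4)
  expect_equal(si$mask, c(1, 1, 1, 1, 0, 0, 0, 0))
  expect_equal(unname(si$channels[5:8, ]), matrix(0, 4, 7))

  long <- make_session(list(make_stroke(seq(0, by = 33, length.out = 20),
                                        1:20, 1:20)), dev)
  si2 <- build_sequence_input(long, max_len = 8)
  expect_equal(si2$n_valid, 8)
  expect_equal(si2$mask, rep(1, 8))
  expect_equal(si2$channels[, "x"], (1:8) / dev$width_px)

  set.seed(3)
  s <- random_session(4)
  si3 <- build_sequence_input(s, max_len = 256)
  expect_equal(sum(si3$channels[, "stroke_start"]), length(s$strokes))
  starts <- which(si3$channels[, "stroke_start"] == 1)
  expect_equal(starts[1], 1)
  # velocity/acceleration channels are zero at every stroke head
  expect_true(all(si3$channels[starts, c("vx", "vy", "ax", "ay")] == 0))
})
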