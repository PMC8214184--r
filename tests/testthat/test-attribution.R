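test_that("Grad-CAM equals the analytic closed form on the toy network", {
  m <- toy_cam_model()
  x <- c(-1, 0.5, 2, -0.3, 1)
  d <- cam_data(x, n_valid = 5)
  map <- grad_cam(m, d, 1)
  relu <- pmax(x, 0)
  expect_equal(map$weights, (relu - min(relu)) / (max(relu) - min(relu)),
               tolerance = 1e-6)
  expect_equal(map$n_valid, 5L)
  # scaling the head (hence the logit) leaves the normalized map unchanged
  map2 <- grad_cam(toy_cam_model(w_head = 7), d, 1)
  expect_equal(map2$weights, map$weights, tolerance = 1e-6)
})

test_that("a zero-gradient all-zero sample yields an all-zero map", {
  m <- toy_cam_model()
  d <- cam_data(rep(0, 5), n_valid = 5)
  map <- grad_cam(m, d, 1)
  expect_equal(map$weights, rep(0, 5))
})

test_that("maps are nonnegative, normalized, and mask-respecting", {
  cfg <- cohort_config(n_typical = 6, n_disability = 6, seed = 19)
  sessions <- generate_cohorts(cfg)
  data <- build_fused_dataset(sessions, max_len = 32)
  mc <- model_config(conv = list(list(filters = 4, kernel = 3, stride = 1),
                                 list(filters = 4, kernel = 3, stride = 1)),
                     dense = 8, epochs = 3, max_len = 32, seed = 5)
  m <- train_model(build_model(mc, ncol(data$fixed), dim(data$seq)[3]), data)
  for (i in c(1, 4, 9)) {
    map <- grad_cam(m, data, i)
    expect_equal(length(map$weights), sum(data$mask[i, ]))
    expect_true(all(map$weights >= 0 & map$weights <= 1))
    if (any(map$weights > 0)) expect_equal(max(map$weights), 1)
  }
  # both conv layers are addressable; unknown layers are named in the error
  expect_s3_class(grad_cam(m, data, 1, layer = "conv1"), "attribution_map")
  expect_error(grad_cam(m, data, 1, layer = "conv9"), "conv1, conv2")
})

test_that("overlay joins weights onto pixel coordinates and checks alignment", {
  cfg <- cohort_config(n_typical = 4, n_disability = 4, seed = 23)
  sessions <- generate_cohorts(cfg)
  data <- build_fused_dataset(sessions, max_len = 32)
  mc <- model_config(epochs = 2, max_len = 32, seed = 6)
  m <- train_model(build_model(mc, ncol(data$fixed), dim(data$seq)[3]), data)
  map <- grad_cam(m, data, 2)
  f <- withr::local_tempfile(fileext = ".csv")
  ov <- overlay_export(map, sessions[[2]], max_len = 32, path = f)
  expect_equal(nrow(ov), map$n_valid)
  expect_true(all(c("step", "t", "x_px", "y_px", "weight") %in% names(ov)))
  expect_equal(read.csv(f)$weight, ov$weight, tolerance = 1e-9)
  # uniform weights land in one color bin: all equal
  mapu <- map; mapu$weights <- rep(1, map$n_valid)
  ovu <- overlay_export(mapu, sessions[[2]], max_len = 32)
  expect_equal(unique(ovu$weight), 1)
  # session/map mismatch is an alignment error
  short <- make_session(list(make_stroke(c(0, 33, 66), 1:3, 1:3)))
  expect_error(overlay_export(map, short, max_len = 32), "alignment")
})

test_that("a trained model concentrates weight on planted wander strokes", {
  # disability sessions start with an erratic off-path stroke before a calm
  # direct one; typical sessions have only the calm stroke. After training,
  # Grad-CAM weight on the wander steps should exceed the direct-path steps.
  set.seed(77)
  dev <- device_info(1280, 800, 6.1)
  calm <- function(t0) {
    m <- stroke_model(c(0.2, 0.8), c(0.8, 0.2), duration = 1.0,
                      amplitude = 0.005, rate = 1, noise_sd = 0.001,
                      phase = runif(2, 0, 2 * pi))
    synthesize_stroke(m, 16, dev, t0_ms = t0)
  }
  wander <- function() {
    m <- stroke_model(runif(2, 0.3, 0.7), runif(2, 0.3, 0.7), duration = 1.0,
                      amplitude = 0.15, rate = 6, noise_sd = 0.02,
                      phase = runif(2, 0, 2 * pi))
    synthesize_stroke(m, 16, dev, t0_ms = 0)
  }
  n <- 30
  sessions <- c(
    lapply(seq_len(n), function(i)
      game_session(sprintf("T%03d", i), "s1", "sixth", list(calm(0)), dev,
                   label = "typical", age_months = 50)),
    lapply(seq_len(n), function(i) {
      w <- wander()
      game_session(sprintf("D%03d", i), "s1", "sixth",
                   list(w, calm(tail(w$events$t, 1) + 400)), dev,
                   label = "disability", age_months = 50)
    }))
  data <- build_fused_dataset(sessions, max_len = 40,
                              fixed_cols = c("age_months", "device_diag_in"))
  mc <- model_config(conv = list(list(filters = 8, kernel = 5, stride = 1)),
                     dense = 8, epochs = 30, max_len = 40, seed = 11)
  m <- train_model(build_model(mc, ncol(data$fixed), dim(data$seq)[3]), data)
  dis_idx <- which(data$y == 1)
  ratio_hits <- 0
  for (i in dis_idx[1:10]) {
    map <- grad_cam(m, data, i)
    si <- build_sequence_input(sessions[[i]], 40)
    boundary <- which(si$channels[seq_len(si$n_valid), "stroke_start"] == 1)
    wander_steps <- seq_len(if (length(boundary) > 1) boundary[2] - 1 else si$n_valid)
    direct_steps <- setdiff(seq_len(si$n_valid), wander_steps)
    if (length(direct_steps) == 0) next
    if (mean(map$weights[wander_steps]) > mean(map$weights[direct_steps]))
      ratio_hits <- ratio_hits + 1
  }
  expect_gte(ratio_hits, 7)
})
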