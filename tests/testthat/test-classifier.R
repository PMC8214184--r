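# small synthetic fused dataset with a plantable signal
toy_dataset <- function(n = 40, L = 16, C = 3, sep = 1, seed = 1) {
  set.seed(seed)
  y <- rep(0:1, length.out = n)
  seqs <- array(rnorm(n * L * C, 0, 0.1), c(n, L, C))
  seqs[y == 1, , 1] <- seqs[y == 1, , 1] + sep
  fixed <- cbind(rnorm(n), y * sep + rnorm(n, 0, 0.1))
  list(seq = seqs, mask = matrix(1, n, L), fixed = fixed, y = y,
       user = sprintf("u%03d", seq_len(n)))
}

toy_config <- function(L = 16, ...) {
  model_config(conv = list(list(filters = 8, kernel = 3, stride = 1)),
               dense = 8, epochs = 20, batch_size = 16, max_len = L,
               dropout = 0, ...)
}

test_that("the forward pass is a deterministic probability in (0, 1)", {
  d <- toy_dataset()
  m <- build_model(toy_config(), n_fixed = 2, n_channels = 3)
  p <- predict_model(m, d)
  expect_true(all(p > 0 & p < 1))
  expect_identical(p, predict_model(m, d))
  # identical samples give identical outputs
  d2 <- d
  d2$seq[2, , ] <- d$seq[1, , ]; d2$fixed[2, ] <- d$fixed[1, ]
  d2$mask[2, ] <- d$mask[1, ]
  p2 <- predict_model(m, d2)
  expect_equal(p2[1], p2[2])
})

test_that("an all-masked sequence with zero fixed input stays finite", {
  d <- toy_dataset(n = 4)
  d$mask[1, ] <- 0
  d$seq[1, , ] <- 0
  d$fixed[1, ] <- 0
  m <- build_model(toy_config(), 2, 3)
  p <- predict_model(m, d)
  expect_true(all(is.finite(p)))
  m2 <- build_model(toy_config(pooling = "global_max"), 2, 3)
  expect_true(all(is.finite(predict_model(m2, d))))
})

test_that("kernels wider than the sequence are rejected", {
  cfg <- model_config(conv = list(list(filters = 2, kernel = 99, stride = 1)),
                      max_len = 16)
  expect_error(build_model(cfg, 2, 3), "exceeds max_len")
})

test_that("analytic gradients match finite differences", {
  d <- toy_dataset(n = 6, L = 8)
  cfg <- model_config(conv = list(list(filters = 3, kernel = 3, stride = 1)),
                      dense = 4, dropout = 0, max_len = 8, l2 = 0, seed = 2)
  m <- build_model(cfg, 2, 3)
  d$mask[2, 6:8] <- 0  # exercise masking
  loss_of <- function(m) {
    cache <- dragkinetics:::nn_forward(m, d$seq, d$mask, d$fixed)
    p <- pmin(pmax(cache$p, 1e-12), 1 - 1e-12)
    -mean(d$y * log(p) + (1 - d$y) * log(1 - p))
  }
  cache <- dragkinetics:::nn_forward(m, d$seq, d$mask, d$fixed)
  g <- dragkinetics:::nn_backward(m, cache, (cache$p - d$y) / length(d$y))
  eps <- 1e-6
  for (probe in list(c("conv", 1, 3), c("dense", 1, 2), c("out", 1, 1))) {
    branch <- probe[1]; i <- as.integer(probe[2]); j <- as.integer(probe[3])
    m_hi <- m; m_lo <- m
    if (branch == "out") {
      m_hi$out$W[j] <- m_hi$out$W[j] + eps
      m_lo$out$W[j] <- m_lo$out$W[j] - eps
      ana <- g$out$W[j]
    } else {
      m_hi[[branch]][[i]]$W[j] <- m_hi[[branch]][[i]]$W[j] + eps
      m_lo[[branch]][[i]]$W[j] <- m_lo[[branch]][[i]]$W[j] - eps
      ana <- g[[branch]][[i]]$W[j]
    }
    num <- (loss_of(m_hi) - loss_of(m_lo)) / (2 * eps)
    expect_equal(ana, num, tolerance = 1e-5)
  }
})

test_that("training separates a linearly separable toy problem", {
  d <- toy_dataset(n = 40, sep = 1.5)
  cfg <- toy_config(seed = 3)
  m <- train_model(build_model(cfg, 2, 3), d)
  expect_gt(auroc(predict_model(m, d), d$y), 0.95)
  # seeded training is run-to-run reproducible
  m2 <- train_model(build_model(cfg, 2, 3), d)
  expect_equal(predict_model(m, d), predict_model(m2, d), tolerance = 1e-12)
})

test_that("folds partition children and stratification is preserved", {
  cfg <- cohort_config(n_typical = 30, n_disability = 30, seed = 15)
  data <- build_fused_dataset(generate_cohorts(cfg), max_len = 32)
  fold <- dragkinetics:::make_folds(data$user, data$y, k = 5, seed = 9)
  expect_length(fold, length(data$y))
  expect_setequal(unique(fold), 1:5)
  # each child appears in exactly one fold; classes spread across folds
  tab <- table(fold, data$y)
  expect_true(all(tab > 0))
  expect_equal(sum(tab), 60)
})

test_that("per-fold standardization uses training-split statistics only", {
  set.seed(6)
  tr <- matrix(rnorm(50, 10, 5), 25, 2)
  te <- matrix(rnorm(10, 10, 5), 5, 2)
  std_tr <- dragkinetics:::standardize_fixed(tr, tr)
  std_te <- dragkinetics:::standardize_fixed(tr, te)
  expect_equal(colMeans(std_tr), c(0, 0), tolerance = 1e-12)
  # test split standardized with the training constants, not its own
  expect_false(isTRUE(all.equal(colMeans(std_te), c(0, 0))))
  back <- sweep(sweep(std_te, 2, apply(tr, 2, sd), "*"), 2, colMeans(tr), "+")
  expect_equal(back, te, tolerance = 1e-10)
})

test_that("cross-validation on separable cohorts reports a full panel", {
  cfg <- cohort_config(n_typical = 25, n_disability = 25, seed = 8)
  data <- build_fused_dataset(generate_cohorts(cfg), max_len = 48)
  cv <- run_cv(data, model_config(epochs = 10, max_len = 48, seed = 2),
               k = 5, seed = 3)
  expect_s3_class(cv, "cv_report")
  expect_equal(nrow(cv$per_fold), 5)
  expect_true(all(cv$per_fold$auroc >= 0 & cv$per_fold$auroc <= 1))
  expect_gt(unname(cv$mean["auroc"]), 0.9)
  expect_true(all(is.finite(cv$scores)))
  expect_error(run_cv(data, model_config(), k = 30, seed = 1),
               "at least k samples")
})

test_that("grid search selects the better configuration and breaks ties", {
  d <- toy_dataset(n = 40, sep = 1.5)
  strong <- toy_config(seed = 4)
  weak <- toy_config(seed = 4)
  weak$epochs <- 1L; weak$lr <- 1e-6  # planted always-underfit rival
  gs <- grid_search(list(weak, strong), d, k_inner = 2, seed = 5)
  expect_equal(gs$best_index, 2)
  # singleton grid returns that config; duplicated configs pick the first
  expect_equal(grid_search(list(strong), d, k_inner = 2, seed = 5)$best_index, 1)
  gs2 <- grid_search(list(strong, strong), d, k_inner = 2, seed = 5)
  expect_equal(gs2$best_index, 1)
})
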