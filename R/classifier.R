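#' Assemble the fused (sequence + fixed) dataset from sessions
#'
#' Builds one fused sample per session: the time-variant channel stack from
#' [build_sequence_input()] plus the time-fixed vector (the kinetic feature
#' battery, age in months, and device diagonal). Children typically
#' contribute one session per subgame; fold assignment downstream is by
#' child, so a child never spans folds.
#'
#' @param sessions list of labeled `game_session` (single subgame).
#' @param max_len sequence length `L`.
#' @param fixed_cols which columns of [features_table()] to use as the
#'   time-fixed vector; the default is the full kinetic battery plus age
#'   and device diagonal. Restricting this (e.g. to
#'   `c("age_months", "device_diag_in")`) isolates the sequence branch for
#'   ablation studies.
#' @return list of class `fused_dataset`: `seq` (B x L x C array), `mask`
#'   (B x L), `fixed` (B x n_fixed matrix, unstandardized), `y` (0/1,
#'   1 = disability), `user` (character), `sessions` (the input list).
#' @export
build_fused_dataset <- function(sessions, max_len = 64L,
                                fixed_cols = c(feature_names(), "age_months",
                                               "device_diag_in")) {
  stopifnot(length(sessions) > 0)
  labs <- vapply(sessions, function(s) s$label, character(1))
  if (anyNA(labs)) stop("all sessions must carry a label")
  sg <- unique(vapply(sessions, function(s) s$subgame, character(1)))
  if (length(sg) > 1) stop("mixed subgames; build one dataset per subgame")
  B <- length(sessions)
  ft <- features_table(sessions)
  fixed <- as.matrix(ft[, fixed_cols, drop = FALSE])
  si <- lapply(sessions, build_sequence_input, max_len = max_len)
  C <- ncol(si[[1]]$channels)
  seq_arr <- array(0, c(B, max_len, C))
  mask <- matrix(0, B, max_len)
  for (i in seq_len(B)) {
    seq_arr[i, , ] <- si[[i]]$channels
    mask[i, ] <- si[[i]]$mask
  }
  structure(list(seq = seq_arr, mask = mask, fixed = fixed,
                 y = as.integer(labs == "disability"), user = ft$user_id,
                 subgame = sg, sessions = sessions),
            class = "fused_dataset")
}

subset_dataset <- function(data, idx) {
  list(seq = data$seq[idx, , , drop = FALSE],
       mask = data$mask[idx, , drop = FALSE],
       fixed = data$fixed[idx, , drop = FALSE],
       y = data$y[idx], user = data$user[idx],
       sessions = data$sessions[idx])
}

# Standardize fixed features with training-split statistics only.
standardize_fixed <- function(train_fixed, apply_to) {
  mu <- colMeans(train_fixed)
  sdv <- apply(train_fixed, 2, sd)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  sweep(sweep(apply_to, 2, mu), 2, sdv, "/")
}

# Seeded stratified fold assignment grouped by child: every session of a
# child lands in the same fold; folds balanced within each class.
make_folds <- function(user, y, k, seed) {
  uu <- unique(user)
  uy <- y[match(uu, user)]
  fold_of <- integer(length(uu)); names(fold_of) <- uu
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  for (cls in unique(uy)) {
    members <- sample(uu[uy == cls])
    fold_of[members] <- rep_len(seq_len(k), length(members))
  }
  unname(fold_of[user])
}

#' Stratified grouped k-fold cross-validation
#'
#' Evaluates the joint-fusion classifier the way the study protocol does:
#' stratified 10-fold cross-validation with folds grouped by child, fixed
#' features standardized with training-fold statistics only, one model
#' trained per fold from a fold-specific seed, and the metric panel
#' aggregated as mean (SD) over folds.
#'
#' @param data a [build_fused_dataset()].
#' @param config a [model_config()].
#' @param k number of folds.
#' @param seed fold-assignment and training seed.
#' @return list of class `cv_report`: `per_fold` (data.frame, one row per
#'   fold), `mean`, `sd` (named vectors over the metric panel), `scores`
#'   (out-of-fold scores, original order), `fold` (fold id per sample),
#'   `k`, `config`.
#' @export
run_cv <- function(data, config, k = 10, seed = 1L) {
  y <- data$y
  if (min(table(y)) < k)
    stop("need at least k samples per class for stratified k-fold")
  fold <- make_folds(data$user, y, k, seed)
  metrics <- list()
  oof <- rep(NA_real_, length(y))
  for (f in seq_len(k)) {
    tr <- which(fold != f); te <- which(fold == f)
    if (length(unique(y[tr])) < 2)
      stop("a class is absent from the training split of fold ", f)
    dtr <- subset_dataset(data, tr)
    dte <- subset_dataset(data, te)
    mu_sd_applied <- standardize_fixed(dtr$fixed, dtr$fixed)
    dte$fixed <- standardize_fixed(dtr$fixed, dte$fixed)
    dtr$fixed <- mu_sd_applied
    cfg <- config; cfg$seed <- config$seed + f
    model <- build_model(cfg, n_fixed = ncol(dtr$fixed),
                         n_channels = dim(dtr$seq)[3])
    model <- train_model(model, dtr)
    sc <- predict_model(model, dte)
    oof[te] <- sc
    metrics[[f]] <- compute_metrics(sc, dte$y)
  }
  per_fold <- as.data.frame(do.call(rbind, metrics))
  per_fold <- cbind(fold = seq_len(k), per_fold)
  structure(list(per_fold = per_fold,
                 mean = colMeans(per_fold[-1], na.rm = TRUE),
                 sd = apply(per_fold[-1], 2, sd, na.rm = TRUE),
                 scores = oof, fold = fold, k = k, config = config),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d-fold cross-validation, %d samples\n",
              x$k, length(x$scores)))
  for (m in names(x$mean))
    cat(sprintf("  %-12s %.3f (%.3f)\n", m, x$mean[m], x$sd[m]))
  invisible(x)
}

#' Exhaustive grid search over model configurations
#'
#' Scores every candidate configuration by inner-cross-validation mean
#' AUROC; ties are broken by smaller parameter count, then grid order.
#'
#' @param grid non-empty list of [model_config()].
#' @param data a [build_fused_dataset()] (training data only).
#' @param k_inner inner CV folds.
#' @param seed inner fold/training seed.
#' @return list with `best` (the winning config), `trace` (data.frame with
#'   one row per candidate: mean AUROC, parameter count, rank).
#' @export
grid_search <- function(grid, data, k_inner = 3, seed = 1L) {
  stopifnot(length(grid) >= 1)
  trace <- data.frame(config = seq_along(grid), mean_auroc = NA_real_,
                      n_params = NA_integer_)
  for (i in seq_along(grid)) {
    cfg <- grid[[i]]
    rep <- run_cv(data, cfg, k = k_inner, seed = seed)
    trace$mean_auroc[i] <- unname(rep$mean["auroc"])
    trace$n_params[i] <- n_params(build_model(cfg, ncol(data$fixed),
                                              dim(data$seq)[3]))
  }
  ord <- order(-trace$mean_auroc, trace$n_params, trace$config)
  trace$rank <- match(seq_along(grid), ord)
  list(best = grid[[ord[1]]], best_index = ord[1], trace = trace)
}
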