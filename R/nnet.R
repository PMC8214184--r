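# Native-R joint-fusion 1D convolutional network.
#
# The model has two branches: a stack of 1D convolutions (ReLU, 'same'
# zero padding) over the per-event channel sequence followed by masked
# global pooling, and a pass-through branch for the time-fixed feature
# vector. The branch outputs are concatenated per child and fed to a dense
# ReLU head with a single sigmoid output (probability of the disability
# class). Training is full backpropagation with Adam on binary
# cross-entropy. Everything operates on batches: sequences as (B, L, C)
# arrays, masks as (B, L) matrices.

#' Model configuration for the joint-fusion classifier
#'
#' @param conv list of convolution blocks, each `list(filters=, kernel=,
#'   stride=)`; applied in order with ReLU. Stride subsamples output
#'   positions.
#' @param pooling `"global_avg"` (mask-weighted mean over time) or
#'   `"global_max"`.
#' @param dense integer vector of hidden widths for the post-fusion head.
#' @param dropout dropout rate in `[0, 1)` applied to dense hidden layers
#'   during training.
#' @param lr Adam learning rate.
#' @param batch_size,epochs SGD schedule.
#' @param max_len sequence length `L` fed to the network (>= 8).
#' @param l2 weight decay coefficient.
#' @param branches which input branches to use; dropping `"sequence"` gives
#'   the fixed-features-only ablation.
#' @param seed integer seed controlling initialization, shuffling and
#'   dropout.
#' @return list of class `model_config`.
#' @export
model_config <- function(conv = list(list(filters = 16, kernel = 5, stride = 1)),
                         pooling = c("global_avg", "global_max"),
                         dense = 16,
                         dropout = 0.1,
                         lr = 0.01,
                         batch_size = 32,
                         epochs = 30,
                         max_len = 64,
                         l2 = 1e-4,
                         branches = c("sequence", "fixed"),
                         seed = 1L) {
  pooling <- match.arg(pooling)
  branches <- match.arg(branches, several.ok = TRUE)
  stopifnot(length(conv) >= 1 || !("sequence" %in% branches),
            dropout >= 0, dropout < 1, lr > 0, batch_size >= 1,
            epochs >= 1, max_len >= 8, l2 >= 0)
  for (bl in conv) stopifnot(bl$filters >= 1, bl$kernel >= 1, bl$stride >= 1)
  structure(list(conv = conv, pooling = pooling, dense = as.integer(dense),
                 dropout = dropout, lr = lr, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), max_len = as.integer(max_len),
                 l2 = l2, branches = branches, seed = as.integer(seed)),
            class = "model_config")
}

glorot <- function(nin, nout) {
  matrix(runif(nin * nout, -1, 1) * sqrt(6 / (nin + nout)), nin, nout)
}

#' Build (initialize) a joint-fusion model
#'
#' Allocates seeded initial weights for the configured architecture. The
#' returned handle is a plain list of weight matrices; [train_model()]
#' returns an updated copy and [predict_model()] runs inference.
#'
#' @param config a [model_config()].
#' @param n_fixed length of the time-fixed feature vector.
#' @param n_channels number of sequence channels.
#' @return list of class `fusion_cnn`.
#' @export
build_model <- function(config, n_fixed, n_channels) {
  stopifnot(inherits(config, "model_config"))
  use_seq <- "sequence" %in% config$branches
  use_fix <- "fixed" %in% config$branches
  if (!use_seq && !use_fix) stop("at least one branch required")
  if (use_seq) {
    for (bl in config$conv)
      if (bl$kernel > config$max_len)
        stop(sprintf("kernel width %d exceeds max_len %d", bl$kernel, config$max_len))
  }
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(config$seed)
  conv <- list()
  cin <- n_channels
  if (use_seq) {
    for (bl in config$conv) {
      conv[[length(conv) + 1]] <- list(W = glorot(bl$kernel * cin, bl$filters),
                                       b = rep(0, bl$filters),
                                       kernel = bl$kernel, stride = bl$stride,
                                       cin = cin, cout = bl$filters)
      cin <- bl$filters
    }
  }
  n_in <- (if (use_seq) cin else 0) + (if (use_fix) n_fixed else 0)
  dense <- list()
  for (w in config$dense) {
    dense[[length(dense) + 1]] <- list(W = glorot(n_in, w), b = rep(0, w))
    n_in <- w
  }
  out <- list(W = glorot(n_in, 1), b = 0)
  structure(list(config = config, n_fixed = n_fixed, n_channels = n_channels,
                 conv = conv, dense = dense, out = out,
                 use_seq = use_seq, use_fix = use_fix),
            class = "fusion_cnn")
}

# -- forward -----------------------------------------------------------------

# im2col for 'same'-padded 1D convolution: X (B, L, C) -> (B, L, k*C)
im2col1d <- function(X, k) {
  B <- dim(X)[1]; L <- dim(X)[2]; C <- dim(X)[3]
  pad <- (k - 1) %/% 2
  P <- array(0, c(B, L, k * C))
  for (j in seq_len(k)) {
    sh <- j - 1 - pad
    tsrc <- seq_len(L) + sh
    sel <- tsrc >= 1 & tsrc <= L
    if (any(sel))
      P[, which(sel), ((j - 1) * C + 1):(j * C)] <- X[, tsrc[sel], , drop = FALSE]
  }
  P
}

# adjoint of im2col1d: dP (B, L, k*C) -> dX (B, L, C)
col2im1d <- function(dP, k, C) {
  B <- dim(dP)[1]; L <- dim(dP)[2]
  pad <- (k - 1) %/% 2
  dX <- array(0, c(B, L, C))
  for (j in seq_len(k)) {
    sh <- j - 1 - pad
    tsrc <- seq_len(L) + sh
    sel <- tsrc >= 1 & tsrc <= L
    if (any(sel))
      dX[, tsrc[sel], ] <- dX[, tsrc[sel], , drop = FALSE] +
        dP[, which(sel), ((j - 1) * C + 1):(j * C), drop = FALSE]
  }
  dX
}

mat3 <- function(A) {  # (B, L, F) -> (B*L, F)
  d <- dim(A); dim(A) <- c(d[1] * d[2], d[3]); A
}
arr3 <- function(M, B, L) { dim(M) <- c(B, L, ncol(M)); M }

nn_forward <- function(model, X, mask, Ffix, training = FALSE) {
  cfg <- model$config
  B <- nrow(mask)
  cache <- list(conv = list())
  if (model$use_seq) {
    A <- X; m <- mask
    for (li in seq_along(model$conv)) {
      ly <- model$conv[[li]]
      P <- im2col1d(A, ly$kernel)
      L <- dim(A)[2]
      Z <- sweep(mat3(P) %*% ly$W, 2, ly$b, "+")
      Zar <- arr3(Z, B, L)
      Aout <- Zar * (Zar > 0)
      # zero out masked steps so pooling and deeper layers ignore padding
      Aout <- Aout * array(rep(m, dim(Aout)[3]), dim(Aout))
      if (ly$stride > 1) {
        pos <- seq(1, L, by = ly$stride)
        Aout <- Aout[, pos, , drop = FALSE]
        Zar <- Zar[, pos, , drop = FALSE]
        m2 <- m[, pos, drop = FALSE]
      } else m2 <- m
      cache$conv[[li]] <- list(P = P, Z = Zar, A = Aout, mask_in = m,
                               mask_out = m2, L_in = L)
      A <- Aout; m <- m2
    }
    nv <- pmax(rowSums(m), 1)
    if (cfg$pooling == "global_avg") {
      pooled <- apply(A, 3, function(s) rowSums(s * m)) / nv
    } else {
      neg <- array(rep(1 - m, dim(A)[3]), dim(A)) * -1e30
      pooled <- apply(A + neg, 3, function(s) apply(s, 1, max))
      pooled[pooled < -1e29] <- 0
    }
    pooled <- matrix(pooled, nrow = B)
    cache$pool <- list(A = A, mask = m, nv = nv, pooled = pooled)
    H <- if (model$use_fix) cbind(pooled, Ffix) else pooled
  } else {
    H <- Ffix
  }
  cache$H0 <- H
  cache$dense <- list()
  for (li in seq_along(model$dense)) {
    ly <- model$dense[[li]]
    Z <- sweep(H %*% ly$W, 2, ly$b, "+")
    A <- Z * (Z > 0)
    drop_mask <- NULL
    if (training && cfg$dropout > 0) {
      drop_mask <- matrix(stats::rbinom(length(A), 1, 1 - cfg$dropout),
                          nrow(A), ncol(A)) / (1 - cfg$dropout)
      A <- A * drop_mask
    }
    cache$dense[[li]] <- list(H_in = H, Z = Z, A = A, drop = drop_mask)
    H <- A
  }
  logit <- drop(H %*% model$out$W + model$out$b)
  cache$H_last <- H
  cache$logit <- logit
  cache$p <- 1 / (1 + exp(-logit))
  cache
}

# Backward pass from d(loss)/d(logit). Returns weight gradients, and when
# `to_conv` is set, stops early and returns d(logit)/d(A) for that conv
# layer's post-ReLU activation (used by Grad-CAM).
nn_backward <- function(model, cache, dlogit, to_conv = NULL) {
  B <- length(dlogit)
  g <- list(conv = list(), dense = list())
  dlog <- matrix(dlogit, ncol = 1)
  g$out <- list(W = t(cache$H_last) %*% dlog, b = sum(dlog))
  dH <- dlog %*% t(model$out$W)
  for (li in rev(seq_along(model$dense))) {
    cc <- cache$dense[[li]]
    dA <- dH
    if (!is.null(cc$drop)) dA <- dA * cc$drop
    dZ <- dA * (cc$Z > 0)
    g$dense[[li]] <- list(W = t(cc$H_in) %*% dZ, b = colSums(dZ))
    dH <- dZ %*% t(model$dense[[li]]$W)
  }
  if (!model$use_seq) return(g)
  n_seq <- ncol(cache$pool$pooled)
  dpool <- dH[, seq_len(n_seq), drop = FALSE]
  pc <- cache$pool
  Fo <- dim(pc$A)[3]; Lo <- dim(pc$A)[2]
  if (model$config$pooling == "global_avg") {
    dA <- array(0, dim(pc$A))
    for (f in seq_len(Fo)) dA[, , f] <- (dpool[, f] / pc$nv) * pc$mask
  } else {
    dA <- array(0, dim(pc$A))
    neg <- array(rep(1 - pc$mask, Fo), dim(pc$A)) * -1e30
    Am <- pc$A + neg
    valid <- rowSums(pc$mask) > 0
    for (f in seq_len(Fo)) {
      amax <- max.col(matrix(Am[, , f], nrow = B), ties.method = "first")
      dA[cbind(seq_len(B), amax, f)] <- dpool[, f] * valid
    }
  }
  for (li in rev(seq_along(model$conv))) {
    cc <- cache$conv[[li]]
    ly <- model$conv[[li]]
    if (!is.null(to_conv) && li == to_conv) return(list(dA = dA))
    # undo stride subsampling
    if (ly$stride > 1) {
      full <- array(0, c(B, cc$L_in, ly$cout))
      pos <- seq(1, cc$L_in, by = ly$stride)
      full[, pos, ] <- dA
      dA <- full
      Zfull <- array(0, dim(full))
      Zfull[, pos, ] <- cc$Z
      Z <- Zfull
      mfull <- cc$mask_in  # mask at stride-1 resolution
    } else {
      Z <- cc$Z
      mfull <- cc$mask_in
    }
    dA <- dA * array(rep(mfull, ly$cout), dim(dA))
    dZ <- dA * (Z > 0)
    dZm <- mat3(dZ)
    g$conv[[li]] <- list(W = t(mat3(cc$P)) %*% dZm, b = colSums(dZm))
    dP <- dZm %*% t(ly$W)
    dA <- col2im1d(arr3(dP, B, cc$L_in), ly$kernel, ly$cin)
  }
  g$dX <- dA
  g
}

# -- training ----------------------------------------------------------------

adam_init <- function(model) {
  zero_like <- function(w) lapply(w[c("W", "b")], function(x) x * 0)
  state <- list(conv = lapply(model$conv, zero_like),
                dense = lapply(model$dense, zero_like),
                out = list(zero_like(model$out)))
  list(m = state, v = state, t = 0)
}

adam_update <- function(w, gw, m, v, t, lr, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  m <- b1 * m + (1 - b1) * gw
  v <- b2 * v + (1 - b2) * gw^2
  mhat <- m / (1 - b1^t); vhat <- v / (1 - b2^t)
  list(w = w - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
}

#' Train a joint-fusion model
#'
#' Minibatch Adam on binary cross-entropy with L2 weight decay. Seeded:
#' identical data, config and seed reproduce the same weights.
#'
#' @param model a [build_model()] handle.
#' @param data a fused dataset (see [build_fused_dataset()]): list with
#'   `seq` (B x L x C array), `mask` (B x L), `fixed` (B x n_fixed), `y`
#'   (0/1 vector).
#' @param verbose print per-epoch loss.
#' @return the trained `fusion_cnn`.
#' @export
train_model <- function(model, data, verbose = FALSE) {
  cfg <- model$config
  B <- length(data$y)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(cfg$seed + 211)
  opt <- adam_init(model)
  for (ep in seq_len(cfg$epochs)) {
    idx <- sample.int(B)
    splits <- split(idx, ceiling(seq_along(idx) / cfg$batch_size))
    ep_loss <- 0
    for (bi in splits) {
      Xb <- data$seq[bi, , , drop = FALSE]
      mb <- data$mask[bi, , drop = FALSE]
      Fb <- data$fixed[bi, , drop = FALSE]
      yb <- data$y[bi]
      cache <- nn_forward(model, Xb, mb, Fb, training = TRUE)
      p <- pmin(pmax(cache$p, 1e-12), 1 - 1e-12)
      ep_loss <- ep_loss - sum(yb * log(p) + (1 - yb) * log(1 - p))
      dlogit <- (cache$p - yb) / length(yb)
      g <- nn_backward(model, cache, dlogit)
      opt$t <- opt$t + 1
      upd <- function(w, gw, branch, li, par) {
        gw <- gw + cfg$l2 * w
        r <- adam_update(w, gw, opt$m[[branch]][[li]][[par]],
                         opt$v[[branch]][[li]][[par]], opt$t, cfg$lr)
        opt$m[[branch]][[li]][[par]] <<- r$m
        opt$v[[branch]][[li]][[par]] <<- r$v
        r$w
      }
      for (li in seq_along(model$conv)) {
        model$conv[[li]]$W <- upd(model$conv[[li]]$W, g$conv[[li]]$W, "conv", li, "W")
        model$conv[[li]]$b <- upd(model$conv[[li]]$b, g$conv[[li]]$b, "conv", li, "b")
      }
      for (li in seq_along(model$dense)) {
        model$dense[[li]]$W <- upd(model$dense[[li]]$W, g$dense[[li]]$W, "dense", li, "W")
        model$dense[[li]]$b <- upd(model$dense[[li]]$b, g$dense[[li]]$b, "dense", li, "b")
      }
      model$out$W <- upd(model$out$W, g$out$W, "out", 1, "W")
      model$out$b <- upd(model$out$b, g$out$b, "out", 1, "b")
    }
    if (verbose) message(sprintf("epoch %d: loss %.4f", ep, ep_loss / B))
  }
  model
}

#' Predict class probabilities
#'
#' Deterministic inference (no dropout) on a fused dataset.
#'
#' @param model a trained `fusion_cnn`.
#' @param data fused dataset (as for [train_model()]; `y` optional).
#' @return numeric vector of disability-class probabilities in `(0, 1)`.
#' @export
predict_model <- function(model, data) {
  cache <- nn_forward(model, data$seq, data$mask, data$fixed, training = FALSE)
  unname(cache$p)
}

n_params <- function(model) {
  s <- length(model$out$W) + length(model$out$b)
  for (l in model$conv) s <- s + length(l$W) + length(l$b)
  for (l in model$dense) s <- s + length(l$W) + length(l$b)
  s
}
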