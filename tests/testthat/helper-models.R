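# One-filter toy network with a hand-derivable Grad-CAM closed form:
# identity kernel, ReLU, global average pooling over the valid steps, and a
# linear head with positive weight w on the pooled feature. The logit is
# w * mean(ReLU(x)), so the pooled gradient is w / n_valid and the Grad-CAM
# map is proportional to ReLU(x).
toy_cam_model <- function(L = 8, w_head = 2) {
  cfg <- model_config(conv = list(list(filters = 1, kernel = 1, stride = 1)),
                      dense = integer(0), dropout = 0, max_len = L, seed = 1)
  m <- build_model(cfg, n_fixed = 1, n_channels = 1)
  m$conv[[1]]$W <- matrix(1, 1, 1)
  m$conv[[1]]$b <- 0
  m$out$W <- matrix(c(w_head, 0), 2, 1)
  m$out$b <- 0
  m
}

cam_data <- function(x, n_valid = length(x), L = 8) {
  seqs <- array(0, c(1, L, 1)); seqs[1, seq_along(x), 1] <- x
  mask <- matrix(0, 1, L); mask[1, seq_len(n_valid)] <- 1
  list(seq = seqs, mask = mask, fixed = matrix(0, 1, 1), y = 1)
}
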