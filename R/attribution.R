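#' Grad-CAM attribution for the sequence branch
#'
#' Gradient-weighted class activation mapping over the 1D convolutional
#' branch: for the chosen conv layer, channel weights are the global time
#' average of the gradient of the positive-class logit with respect to the
#' layer's post-ReLU feature maps; the map is the ReLU of the
#' channel-weighted sum of feature maps, linearly interpolated from the
#' layer's time resolution to the unmasked input length and min-max
#' normalized to `[0, 1]` (normalization is skipped for an all-zero map).
#' Masked (padded) steps carry no weight and are excluded.
#'
#' @param model a trained `fusion_cnn` with a sequence branch.
#' @param data a fused dataset (fixed features standardized as at training
#'   time).
#' @param index which sample of `data` to explain.
#' @param layer conv layer name (`"conv1"`, `"conv2"`, ...); default the
#'   last convolutional layer.
#' @return list of class `attribution_map`: `weights` (length = number of
#'   unmasked steps, in `[0, 1]`), `layer`, `n_valid`, `score` (the model's
#'   positive-class probability for the sample).
#' @export
grad_cam <- function(model, data, index = 1, layer = NULL) {
  stopifnot(inherits(model, "fusion_cnn"))
  if (!model$use_seq) stop("model has no sequence branch to attribute")
  layer_names <- paste0("conv", seq_along(model$conv))
  if (is.null(layer)) layer <- layer_names[length(layer_names)]
  li <- match(layer, layer_names)
  if (is.na(li))
    stop("layer '", layer, "' not found; available: ",
         paste(layer_names, collapse = ", "))
  d <- subset_dataset(data, index)
  cache <- nn_forward(model, d$seq, d$mask, d$fixed, training = FALSE)
  grads <- nn_backward(model, cache, dlogit = 1, to_conv = li)$dA
  cc <- cache$conv[[li]]
  mlay <- cc$mask_out[1, ]
  valid <- which(mlay == 1)
  n_in <- sum(d$mask[1, ])
  if (length(valid) == 0 || n_in == 0) {
    return(structure(list(weights = numeric(0), layer = layer,
                          n_valid = 0L, score = unname(cache$p)),
                     class = "attribution_map"))
  }
  A <- cc$A[1, valid, , drop = FALSE]
  G <- grads[1, valid, , drop = FALSE]
  alpha <- apply(G, 3, mean)                       # pooled gradient weights
  cam <- as.numeric(matrix(A, nrow = length(valid)) %*% alpha)
  cam <- pmax(cam, 0)
  # interpolate from layer resolution to input resolution
  if (length(cam) == 1) {
    w <- rep(cam, n_in)
  } else if (length(cam) == n_in) {
    w <- cam
  } else {
    w <- stats::approx(seq(0, 1, length.out = length(cam)), cam,
                       xout = seq(0, 1, length.out = n_in))$y
  }
  mx <- max(w); mn <- min(w)
  if (mx > 0) {
    w <- if (mx > mn) (w - mn) / (mx - mn) else rep(1, n_in)
  } else {
    w <- rep(0, n_in)
  }
  structure(list(weights = w, layer = layer, n_valid = as.integer(n_in),
                 score = unname(cache$p)),
            class = "attribution_map")
}

#' Export an attribution map overlaid on touch coordinates
#'
#' Joins Grad-CAM step weights back onto the session's pixel coordinates —
#' the overlay used to inspect which parts of a drag the network keyed on.
#' Optionally renders a PNG with a blue-to-red colormap (low weight blue,
#' high weight red) over the game canvas.
#'
#' @param map an [grad_cam()] `attribution_map`.
#' @param session the `game_session` the map was computed from.
#' @param max_len the sequence length the model used.
#' @param path optional CSV output path.
#' @param png_path optional PNG output path.
#' @return data.frame with one row per attributed step: `step`, `t`,
#'   `x_px`, `y_px`, `weight`.
#' @export
overlay_export <- function(map, session, max_len = 64L, path = NULL,
                           png_path = NULL) {
  stopifnot(inherits(map, "attribution_map"))
  si <- build_sequence_input(session, max_len)
  if (si$n_valid != map$n_valid)
    stop(sprintf("alignment error: map has %d steps, session yields %d",
                 map$n_valid, si$n_valid))
  out <- cbind(step = seq_len(si$n_valid), si$coords,
               weight = if (si$n_valid) map$weights else numeric(0))
  rownames(out) <- NULL
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  if (!is.null(png_path) && nrow(out) > 0) {
    ramp <- grDevices::colorRamp(c("blue", "red"))
    cols <- grDevices::rgb(ramp(out$weight), maxColorValue = 255)
    grDevices::png(png_path, width = 800, height = 500)
    on.exit(grDevices::dev.off())
    graphics::plot(out$x_px, -out$y_px, col = cols, pch = 16,
                   xlim = c(0, session$device$width_px),
                   ylim = c(-session$device$height_px, 0),
                   xlab = "x (px)", ylab = "-y (px)",
                   main = sprintf("Grad-CAM overlay (%s, score %.2f)",
                                  map$layer, map$score))
  }
  out
}
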