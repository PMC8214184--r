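#' Per-axis position/velocity/acceleration series for one stroke
#'
#' Decomposes a stroke's trace along one screen axis. Positions are pixels
#' divided by the corresponding device dimension; velocity is the first
#' difference of position over time (length n-1) and acceleration the first
#' difference of velocity (length n-2), with the time step for acceleration
#' taken between velocity midpoints. Events sharing a timestamp are collapsed
#' (the last sample wins) before differencing, so the series never divides by
#' a zero time step.
#'
#' @param stroke a [stroke()].
#' @param device a [device_info()].
#' @param axis `"x"` or `"y"`.
#' @return list of class `axis_series` with fields `t` (seconds), `position`
#'   (normalized units), `velocity` (units/s), `acceleration` (units/s^2),
#'   `axis`. A stroke with fewer than two distinct timestamps yields empty
#'   derivative series.
#' @export
derive_axis_series <- function(stroke, device, axis = c("x", "y")) {
  axis <- match.arg(axis)
  dim_px <- if (axis == "x") device$width_px else device$height_px
  ev <- stroke$events
  t <- ev$t / 1000
  p <- ev[[axis]] / dim_px
  # collapse duplicate timestamps, keep the last sample at each time
  keep <- c(t[-1] != t[-length(t)], TRUE)
  t <- t[keep]; p <- p[keep]
  n <- length(t)
  if (n < 2) {
    return(structure(list(t = t, position = p, velocity = numeric(0),
                          acceleration = numeric(0), axis = axis),
                     class = "axis_series"))
  }
  dt <- diff(t)
  v <- diff(p) / dt
  if (n < 3) {
    a <- numeric(0)
  } else {
    mid <- (t[-1] + t[-n]) / 2  # velocity sample times
    a <- diff(v) / diff(mid)
  }
  structure(list(t = t, position = p, velocity = v, acceleration = a,
                 axis = axis),
            class = "axis_series")
}

#' Count sign changes in a signed series
#'
#' The sign-change volatility count: the number of adjacent pairs of nonzero
#' signs that differ. Zeros are transparent — the last nonzero sign carries
#' across a run of zeros, so a stationary hold between two same-signed
#' movements mints no reversal.
#'
#' @param x numeric vector.
#' @return integer count (0 for length < 2 or all-zero input).
#' @export
count_sign_changes <- function(x) {
  s <- sign(x)
  s <- s[s != 0]
  if (length(s) < 2) return(0L)
  sum(s[-1] != s[-length(s)])
}

#' Names of the kinetic feature battery
#'
#' Column names of the per-session movement statistics produced by
#' [extract_features()], in report order.
#'
#' @return character vector.
#' @export
feature_names <- function() {
  c("playtime_s", "line_number", "line_length_mean", "release_to_touch_s",
    "height_mean_ratio", "height_max_ratio", "width_max_ratio",
    "vel_sign_changes_x", "vel_sign_changes_y",
    "acc_sign_changes_x", "acc_sign_changes_y",
    "vel_sign_changes_x_per_line", "vel_sign_changes_y_per_line",
    "acc_sign_changes_x_per_line", "acc_sign_changes_y_per_line")
}

#' Extract the time-fixed kinetic feature battery from one session
#'
#' Computes the per-session movement statistics used as digital biomarkers:
#' playtime, stroke ("line") count, mean normalized stroke path length,
#' summed release-to-touch gap, touch-region extent ratios, and per-axis
#' velocity/acceleration sign-change counts (total and per line).
#'
#' Conventions: path length is the summed Euclidean pixel step length divided
#' by the pixel screen diagonal; region ratios are per-stroke extents
#' (max - min over the stroke, as a fraction of the screen dimension)
#' aggregated by mean or max over strokes; release-to-touch is the sum of the
#' gaps between each stroke's `up` and the next stroke's `down`, skipping
#' gaps that follow a truncated stroke; derivatives are computed within
#' strokes only, never across a finger lift.
#'
#' @param session a `game_session`.
#' @return one-row data.frame of class `kinetic_features` with the columns of
#'   `feature_names()` plus a logical `degenerate` flag (all-zero features for
#'   an empty session).
#' @export
extract_features <- function(session) {
  stopifnot(inherits(session, "game_session"))
  strokes <- session$strokes
  dev <- session$device
  out <- as.list(setNames(numeric(length(feature_names())), feature_names()))
  if (length(strokes) == 0) {
    res <- as.data.frame(out)
    res$degenerate <- TRUE
    class(res) <- c("kinetic_features", class(res))
    return(res)
  }
  ev_all <- session_events(session)
  out$playtime_s <- (max(ev_all$t) - min(ev_all$t)) / 1000
  out$line_number <- length(strokes)
  diag_px <- sqrt(dev$width_px^2 + dev$height_px^2)
  lens <- h_ext <- w_ext <- numeric(length(strokes))
  vx <- vy <- ax <- ay <- 0L
  for (i in seq_along(strokes)) {
    ev <- strokes[[i]]$events
    lens[i] <- sum(sqrt(diff(ev$x)^2 + diff(ev$y)^2)) / diag_px
    h_ext[i] <- (max(ev$y) - min(ev$y)) / dev$height_px
    w_ext[i] <- (max(ev$x) - min(ev$x)) / dev$width_px
    sx <- derive_axis_series(strokes[[i]], dev, "x")
    sy <- derive_axis_series(strokes[[i]], dev, "y")
    vx <- vx + count_sign_changes(sx$velocity)
    vy <- vy + count_sign_changes(sy$velocity)
    ax <- ax + count_sign_changes(sx$acceleration)
    ay <- ay + count_sign_changes(sy$acceleration)
  }
  out$line_length_mean <- mean(lens)
  out$height_mean_ratio <- mean(h_ext)
  out$height_max_ratio <- max(h_ext)
  out$width_max_ratio <- max(w_ext)
  if (length(strokes) > 1) {
    gap <- 0
    for (i in seq_len(length(strokes) - 1)) {
      if (strokes[[i]]$truncated) next  # no true release time observed
      up_t <- tail(strokes[[i]]$events$t, 1)
      down_t <- strokes[[i + 1]]$events$t[1]
      gap <- gap + (down_t - up_t) / 1000
    }
    out$release_to_touch_s <- gap
  }
  out$vel_sign_changes_x <- vx; out$vel_sign_changes_y <- vy
  out$acc_sign_changes_x <- ax; out$acc_sign_changes_y <- ay
  nl <- max(out$line_number, 1)
  out$vel_sign_changes_x_per_line <- vx / nl
  out$vel_sign_changes_y_per_line <- vy / nl
  out$acc_sign_changes_x_per_line <- ax / nl
  out$acc_sign_changes_y_per_line <- ay / nl
  res <- as.data.frame(out)
  res$degenerate <- FALSE
  class(res) <- c("kinetic_features", class(res))
  res
}

#' Feature table for a set of sessions
#'
#' Applies [extract_features()] to each session and binds the results with
#' identifying metadata, giving the per-(user, session, subgame) feature
#' matrix consumed by the comparison protocol and the classifier.
#'
#' @param sessions list of `game_session`.
#' @return data.frame with `user_id`, `session_id`, `subgame`, `label`,
#'   `age_months`, `device_diag_in` and one column per kinetic feature.
#' @export
features_table <- function(sessions) {
  rows <- lapply(sessions, function(s) {
    cbind(data.frame(user_id = s$user_id, session_id = s$session_id,
                     subgame = s$subgame, label = s$label,
                     age_months = s$age_months,
                     device_diag_in = s$device$diagonal_in,
                     stringsAsFactors = FALSE),
          as.data.frame(extract_features(s)))
  })
  if (length(rows) == 0) {
    return(data.frame(user_id = character(0), session_id = character(0),
                      subgame = character(0), label = character(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build the time-variant channel stack for the sequence branch
#'
#' Concatenates the session's strokes in time order into a fixed-length
#' multichannel sequence: normalized x and y position, per-axis velocity and
#' acceleration (zero-padded at each stroke head so all channels share the
#' event grid), and a stroke-boundary indicator that is 1 exactly at each
#' stroke's first step. Sequences longer than `max_len` keep their first
#' `max_len` steps; shorter ones are zero-padded with `mask = 0` on the tail.
#'
#' @param session a `game_session`.
#' @param max_len target length `L` (>= 8).
#' @return list of class `sequence_input`: `channels` (`L x 7` matrix with
#'   named columns), `mask` (length-`L` 0/1 vector), `n_valid`, and `coords`
#'   (data.frame `t`, `x_px`, `y_px` of the unpadded steps, for attribution
#'   overlays).
#' @export
build_sequence_input <- function(session, max_len = 64L) {
  stopifnot(max_len >= 8)
  ch_names <- c("x", "y", "vx", "vy", "ax", "ay", "stroke_start")
  steps <- list(); coords <- list()
  for (s in session$strokes) {
    sx <- derive_axis_series(s, session$device, "x")
    sy <- derive_axis_series(s, session$device, "y")
    n <- length(sx$t)
    if (n == 0) next
    pad1 <- function(v, len) c(rep(0, len - length(v)), v)
    m <- cbind(x = sx$position, y = sy$position,
               vx = pad1(sx$velocity, n), vy = pad1(sy$velocity, n),
               ax = pad1(sx$acceleration, n), ay = pad1(sy$acceleration, n),
               stroke_start = c(1, rep(0, n - 1)))
    steps[[length(steps) + 1]] <- m
    coords[[length(coords) + 1]] <- data.frame(
      t = sx$t * 1000,
      x_px = sx$position * session$device$width_px,
      y_px = sy$position * session$device$height_px)
  }
  full <- if (length(steps)) do.call(rbind, steps) else
    matrix(0, 0, length(ch_names), dimnames = list(NULL, ch_names))
  co <- if (length(coords)) do.call(rbind, coords) else
    data.frame(t = numeric(0), x_px = numeric(0), y_px = numeric(0))
  n <- nrow(full)
  if (n > max_len) {
    full <- full[seq_len(max_len), , drop = FALSE]
    co <- co[seq_len(max_len), , drop = FALSE]
    n <- max_len
  }
  channels <- matrix(0, max_len, length(ch_names),
                     dimnames = list(NULL, ch_names))
  if (n > 0) channels[seq_len(n), ] <- full
  mask <- c(rep(1, n), rep(0, max_len - n))
  rownames(co) <- NULL
  structure(list(channels = channels, mask = mask, n_valid = n, coords = co),
            class = "sequence_input")
}
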