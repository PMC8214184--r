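# Independent brute-force oracles and fixture builders. Everything here is
# written as direct loops over events, deliberately avoiding the package's
# vectorized implementation paths.

default_device <- function() device_info(1000, 800, 8)

# build a stroke from coordinate vectors (t in ms)
make_stroke <- function(t, x, y) {
  n <- length(t)
  stroke(data.frame(t = t, x = x, y = y,
                    phase = c("down", rep("move", max(0, n - 2)), if (n > 1) "up")))
}

make_session <- function(strokes, device = default_device(), label = "typical",
                         subgame = "sixth", user = "u1", session = "s1",
                         age = 48) {
  game_session(user, session, subgame, strokes, device, label = label,
               age_months = age)
}

# random session with n_strokes random-walk strokes
random_session <- function(n_strokes, device = default_device(),
                           n_events_range = c(2, 30), label = "typical",
                           user = "u1") {
  t0 <- 0
  strokes <- lapply(seq_len(n_strokes), function(i) {
    n <- sample(n_events_range[1]:n_events_range[2], 1)
    t <- t0 + cumsum(c(0, sample(c(0L, 16L, 33L, 50L), n - 1, replace = TRUE)))
    t0 <<- max(t) + sample(100:1500, 1)
    make_stroke(t,
                pmin(pmax(cumsum(rnorm(n, 0, 40)) + device$width_px / 2, 0),
                     device$width_px),
                pmin(pmax(cumsum(rnorm(n, 0, 40)) + device$height_px / 2, 0),
                     device$height_px))
  })
  make_session(strokes, device, label = label, user = user)
}

# -- kinetic feature oracle: direct loops over events ------------------------

oracle_sign_changes <- function(x) {
  last <- 0; count <- 0L
  for (v in x) {
    s <- sign(v)
    if (s == 0) next
    if (last != 0 && s != last) count <- count + 1L
    last <- s
  }
  count
}

oracle_axis_derivs <- function(ev, dim_px, axis) {
  t <- c(); p <- c()
  for (i in seq_len(nrow(ev))) {  # collapse duplicate times, keep last
    ti <- ev$t[i] / 1000; pi <- ev[[axis]][i] / dim_px
    if (length(t) > 0 && ti == t[length(t)]) {
      p[length(p)] <- pi
    } else {
      t <- c(t, ti); p <- c(p, pi)
    }
  }
  n <- length(t)
  v <- c(); a <- c()
  if (n >= 2) for (i in seq_len(n - 1)) v[i] <- (p[i + 1] - p[i]) / (t[i + 1] - t[i])
  if (n >= 3) {
    mid <- c()
    for (i in seq_len(n - 1)) mid[i] <- (t[i] + t[i + 1]) / 2
    for (i in seq_len(n - 2)) a[i] <- (v[i + 1] - v[i]) / (mid[i + 1] - mid[i])
  }
  list(t = t, p = p, v = v, a = a)
}

oracle_features <- function(session) {
  strokes <- session$strokes
  dev <- session$device
  stopifnot(length(strokes) > 0)
  tmin <- Inf; tmax <- -Inf
  for (s in strokes) for (tt in s$events$t) {
    if (tt < tmin) tmin <- tt
    if (tt > tmax) tmax <- tt
  }
  diag_px <- sqrt(dev$width_px^2 + dev$height_px^2)
  lens <- c(); h <- c(); w <- c()
  vx <- 0L; vy <- 0L; ax <- 0L; ay <- 0L
  for (s in strokes) {
    ev <- s$events
    steps <- c()
    for (i in seq_len(nrow(ev) - 1))
      steps[i] <- sqrt((ev$x[i + 1] - ev$x[i])^2 + (ev$y[i + 1] - ev$y[i])^2)
    lens <- c(lens, sum(steps) / diag_px)
    h <- c(h, (max(ev$y) - min(ev$y)) / dev$height_px)
    w <- c(w, (max(ev$x) - min(ev$x)) / dev$width_px)
    dx <- oracle_axis_derivs(ev, dev$width_px, "x")
    dy <- oracle_axis_derivs(ev, dev$height_px, "y")
    vx <- vx + oracle_sign_changes(dx$v); vy <- vy + oracle_sign_changes(dy$v)
    ax <- ax + oracle_sign_changes(dx$a); ay <- ay + oracle_sign_changes(dy$a)
  }
  gap <- 0
  if (length(strokes) > 1)
    for (i in seq_len(length(strokes) - 1)) {
      if (strokes[[i]]$truncated) next
      ev <- strokes[[i]]$events
      gap <- gap + (strokes[[i + 1]]$events$t[1] - ev$t[nrow(ev)]) / 1000
    }
  nl <- max(length(strokes), 1)
  list(playtime_s = (tmax - tmin) / 1000, line_number = length(strokes),
       line_length_mean = mean(lens), release_to_touch_s = gap,
       height_mean_ratio = mean(h), height_max_ratio = max(h),
       width_max_ratio = max(w),
       vel_sign_changes_x = vx, vel_sign_changes_y = vy,
       acc_sign_changes_x = ax, acc_sign_changes_y = ay,
       vel_sign_changes_x_per_line = vx / nl,
       vel_sign_changes_y_per_line = vy / nl,
       acc_sign_changes_x_per_line = ax / nl,
       acc_sign_changes_y_per_line = ay / nl)
}

# -- statistics oracles ------------------------------------------------------

oracle_cles <- function(a, b) {
  wins <- 0
  for (ai in a) for (bi in b) {
    if (ai > bi) wins <- wins + 1
    else if (ai == bi) wins <- wins + 0.5
  }
  wins / (length(a) * length(b))
}

# U statistic by pairwise comparison (no ranks)
oracle_u <- function(a, b) {
  u <- 0
  for (ai in a) for (bi in b) {
    if (ai > bi) u <- u + 1
    else if (ai == bi) u <- u + 0.5
  }
  u
}

# exact two-sided Mann-Whitney p by enumerating all group assignments of the
# pooled values, with U computed pairwise (independent of the rank route)
oracle_mw_p <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  u_obs <- oracle_u(a, b)
  combos <- utils::combn(length(pooled), na)
  u_all <- apply(combos, 2, function(ix) oracle_u(pooled[ix], pooled[-ix]))
  eps <- 1e-9
  min(1, 2 * min(mean(u_all <= u_obs + eps), mean(u_all >= u_obs - eps)))
}

# AUROC by explicit positive-negative pair counting
oracle_auroc <- function(scores, labels) {
  ps <- scores[labels == 1]; ns <- scores[labels == 0]
  if (length(ps) == 0 || length(ns) == 0) return(NA_real_)
  conc <- 0
  for (p in ps) for (n in ns) {
    if (p > n) conc <- conc + 1
    else if (p == n) conc <- conc + 0.5
  }
  conc / (length(ps) * length(ns))
}
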