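#' Cohort generator configuration
#'
#' Parameters of the two-cohort synthetic session generator. Each child
#' contributes `sessions_per_child` sessions of one subgame; per-group
#' parameters are length-2 vectors named `typical` / `disability`.
#'
#' Defaults are loosely anchored to the published cohort summaries for a
#' sixth-subgame-like drag task: ages around 40 vs 72 months; lognormal
#' playtimes with medians near 7.9 vs 4.3 s; about 3 vs 2 strokes per
#' session; a higher micro-oscillation rate in the typical group (driving
#' more velocity/acceleration sign changes) and a higher off-target
#' "wander" probability in the disability group. They are calibration
#' anchors for a plausible synthetic world, not estimates of any real cohort.
#'
#' @param n_typical,n_disability number of children per group.
#' @param subgame which drag-and-drop subgame to label sessions with.
#' @param sessions_per_child sessions generated per child.
#' @param sample_hz touch-event logging rate (events/second).
#' @param playtime_meanlog,playtime_sdlog lognormal per-stroke-duration
#'   parameters (log-seconds), per group. The defaults put the resulting
#'   whole-session playtime medians near 7.9 s (typical) and 4.9 s
#'   (disability) once stroke counts and inter-stroke gaps are included.
#' @param strokes_per_session_mean Poisson mean stroke count per session
#'   (clamped to >= 1), per group.
#' @param oscillation_amplitude sinusoidal jitter amplitude in normalized
#'   screen units, per group.
#' @param oscillation_rate jitter sinusoid frequency in cycles/second; each
#'   cycle contributes two velocity direction reversals, so a stroke of
#'   duration `d` shows about `2 * rate * d` per-axis sign changes, per group.
#' @param noise_sd Gaussian per-sample coordinate noise (normalized units),
#'   per group.
#' @param wander_prob probability that a stroke is preceded by an off-target
#'   excursion stroke toward a random non-goal point, per group.
#' @param age_median,age_iqr age in months: median and interquartile range,
#'   per group (normal approximation, clamped to 12-120 months).
#' @param gap_mean_s mean exponential release-to-touch gap between strokes
#'   (seconds).
#' @param device_pool list of [device_info()] to sample from (non-empty).
#' @param seed integer master seed; every child draws from an independent
#'   substream derived from `(seed, user_id)`, so cohorts are extensible
#'   without reshuffling.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_typical = 200,
                          n_disability = 150,
                          subgame = "sixth",
                          sessions_per_child = 1,
                          sample_hz = 30,
                          playtime_meanlog = c(typical = log(1.8), disability = log(1.4)),
                          playtime_sdlog = c(typical = 0.9, disability = 1.0),
                          strokes_per_session_mean = c(typical = 3, disability = 2),
                          oscillation_amplitude = c(typical = 0.03, disability = 0.03),
                          oscillation_rate = c(typical = 3.0, disability = 1.5),
                          noise_sd = c(typical = 0.0005, disability = 0.0005),
                          wander_prob = c(typical = 0.05, disability = 0.35),
                          age_median = c(typical = 40, disability = 72),
                          age_iqr = c(typical = 12, disability = 32.5),
                          gap_mean_s = 0.5,
                          device_pool = default_device_pool(),
                          seed = 1L) {
  cfg <- list(n_typical = n_typical, n_disability = n_disability,
              subgame = match.arg(subgame, SUBGAMES),
              sessions_per_child = sessions_per_child, sample_hz = sample_hz,
              playtime_meanlog = grp(playtime_meanlog),
              playtime_sdlog = grp(playtime_sdlog),
              strokes_per_session_mean = grp(strokes_per_session_mean),
              oscillation_amplitude = grp(oscillation_amplitude),
              oscillation_rate = grp(oscillation_rate),
              noise_sd = grp(noise_sd),
              wander_prob = grp(wander_prob),
              age_median = grp(age_median), age_iqr = grp(age_iqr),
              gap_mean_s = gap_mean_s,
              device_pool = device_pool, seed = as.integer(seed))
  stopifnot(cfg$n_typical >= 0, cfg$n_disability >= 0,
            cfg$sample_hz > 0, cfg$sessions_per_child >= 1,
            all(cfg$wander_prob >= 0 & cfg$wander_prob <= 1),
            all(cfg$oscillation_rate >= 0), all(cfg$oscillation_amplitude >= 0),
            all(cfg$noise_sd >= 0))
  if (length(device_pool) == 0) stop("device_pool must contain at least one device")
  stopifnot(all(vapply(device_pool, inherits, logical(1), "device_info")))
  structure(cfg, class = "cohort_config")
}

# normalize a per-group parameter to a named length-2 vector
grp <- function(x) {
  if (length(x) == 1) x <- c(typical = unname(x), disability = unname(x))
  stopifnot(length(x) == 2)
  if (is.null(names(x))) names(x) <- LABELS
  x[LABELS]
}

#' @export
default_device_pool <- function() {
  list(device_info(1280, 800, 6.1),
       device_info(1920, 1200, 10.1),
       device_info(1024, 768, 7.9))
}

# Deterministic 31-bit hash of a string, for per-child RNG substreams.
str_hash31 <- function(s) {
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

#' Stroke trajectory model
#'
#' One planned drag: straight drift from `start` to `goal` over `duration`
#' seconds, plus per-axis sinusoidal micro-oscillation (`amplitude` in
#' normalized units, `rate` direction reversals/second, per-axis `phase`)
#' and Gaussian per-sample noise.
#'
#' @param start,goal length-2 points in the unit square.
#' @param duration stroke duration in seconds (> 0).
#' @param amplitude,rate,noise_sd jitter parameters.
#' @param phase length-2 phase offsets (radians) for the x/y sinusoids.
#' @return list of class `stroke_model`.
#' @export
stroke_model <- function(start, goal, duration, amplitude = 0, rate = 0,
                         noise_sd = 0, phase = c(0, 0)) {
  stopifnot(length(start) == 2, length(goal) == 2,
            all(start >= 0 & start <= 1), all(goal >= 0 & goal <= 1))
  structure(list(start = start, goal = goal, duration = duration,
                 amplitude = amplitude, rate = rate, noise_sd = noise_sd,
                 phase = phase),
            class = "stroke_model")
}

#' Synthesize one stroke from a trajectory model
#'
#' Samples the model at approximately `hz` events/second: linear start-to-goal
#' drift plus `amplitude * sin(2 * pi * rate * t + phase)` on each axis plus
#' Gaussian noise, clamped to the unit square and scaled to device pixels.
#' A sinusoid at `r` cycles/second reverses direction twice per cycle, so
#' over duration `d` the oscillating axis shows about `2 * r * d` velocity
#' sign changes (and the same count for acceleration).
#'
#' @param model a [stroke_model()].
#' @param hz sampling rate (> 0).
#' @param device a [device_info()].
#' @param t0_ms stroke start time in ms since session start.
#' @return a [stroke()] with strictly increasing timestamps, first event
#'   `down`, last `up`; degenerate durations yield a 2-event down/up tap.
#' @details Uses the current RNG state; seed management is the caller's
#'   responsibility (see [generate_cohorts()]).
#' @export
synthesize_stroke <- function(model, hz, device, t0_ms = 0) {
  stopifnot(hz > 0)
  d <- model$duration
  if (!is.finite(d) || d <= 0) {
    warning("non-positive duration clamped to one sample interval")
    d <- 1 / hz
  }
  n <- max(2L, as.integer(round(d * hz)) + 1L)
  tt <- seq(0, d, length.out = n)
  osc <- function(ph) model$amplitude * sin(2 * pi * model$rate * tt + ph)
  x <- model$start[1] + (model$goal[1] - model$start[1]) * tt / d +
    osc(model$phase[1]) + rnorm(n, 0, model$noise_sd)
  y <- model$start[2] + (model$goal[2] - model$start[2]) * tt / d +
    osc(model$phase[2]) + rnorm(n, 0, model$noise_sd)
  x <- pmin(pmax(x, 0), 1) * device$width_px
  y <- pmin(pmax(y, 0), 1) * device$height_px
  t_ms <- t0_ms + round(tt * 1000)
  if (any(diff(t_ms) <= 0))  # sub-ms sampling: fall back to 1 ms spacing
    t_ms <- t0_ms + seq(0, by = max(1, round(1000 / hz)), length.out = n)
  stroke(data.frame(t = t_ms,
                    x = round(x, 3), y = round(y, 3),
                    phase = c("down", rep("move", n - 2), "up")))
}

#' Generate two synthetic cohorts of drag-and-drop sessions
#'
#' Produces labeled `game_session`s for `n_typical` children with typical
#' development and `n_disability` children with developmental disabilities,
#' with the group contrasts the downstream analysis expects built in: the
#' typical group oscillates faster (more velocity/acceleration sign changes)
#' and plays longer, while the disability group more often wanders off
#' target before the direct path. Identical config and seed give
#' byte-identical logs; each child has an independent RNG substream, so
#' enlarging one group never changes the other children's sessions.
#'
#' @param config a [cohort_config()].
#' @return list of `game_session` (typical children first), each passing
#'   [validate_session()].
#' @export
generate_cohorts <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  users <- c(if (config$n_typical > 0)
               sprintf("T%04d", seq_len(config$n_typical)),
             if (config$n_disability > 0)
               sprintf("D%04d", seq_len(config$n_disability)))
  labels <- rep(LABELS, c(config$n_typical, config$n_disability))
  sessions <- list()
  for (i in seq_along(users)) {
    sessions <- c(sessions, generate_child(users[i], labels[i], config))
  }
  sessions
}

generate_child <- function(user_id, label, cfg) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed((cfg$seed * 7919 + str_hash31(user_id)) %% 2147483647)

  g <- label
  age_sd <- cfg$age_iqr[g] / 1.349  # IQR of a normal = 1.349 sd
  age <- as.integer(min(max(round(rnorm(1, cfg$age_median[g], age_sd)), 12), 120))
  device <- cfg$device_pool[[sample.int(length(cfg$device_pool), 1)]]

  out <- vector("list", cfg$sessions_per_child)
  for (si in seq_len(cfg$sessions_per_child)) {
    n_strokes <- max(1L, rpois(1, cfg$strokes_per_session_mean[g]))
    t_ms <- 0
    strokes <- list()
    for (k in seq_len(n_strokes)) {
      start <- runif(2, 0.1, 0.9)
      goal <- runif(2, 0.1, 0.9)
      if (runif(1) < cfg$wander_prob[g]) {
        # off-target excursion toward a random non-goal point first
        wander_goal <- runif(2, 0.05, 0.95)
        wm <- stroke_model(start, wander_goal,
                           duration = rlnorm(1, cfg$playtime_meanlog[g] - log(2),
                                             cfg$playtime_sdlog[g]),
                           amplitude = cfg$oscillation_amplitude[g],
                           rate = cfg$oscillation_rate[g],
                           noise_sd = cfg$noise_sd[g],
                           phase = runif(2, 0, 2 * pi))
        ws <- synthesize_stroke(wm, cfg$sample_hz, device, t0_ms = t_ms)
        strokes[[length(strokes) + 1]] <- ws
        t_ms <- tail(ws$events$t, 1) + round(1000 * rexp(1, 1 / cfg$gap_mean_s))
        start <- wander_goal
      }
      m <- stroke_model(start, goal,
                        duration = rlnorm(1, cfg$playtime_meanlog[g],
                                          cfg$playtime_sdlog[g]),
                        amplitude = cfg$oscillation_amplitude[g],
                        rate = cfg$oscillation_rate[g],
                        noise_sd = cfg$noise_sd[g],
                        phase = runif(2, 0, 2 * pi))
      st <- synthesize_stroke(m, cfg$sample_hz, device, t0_ms = t_ms)
      strokes[[length(strokes) + 1]] <- st
      t_ms <- tail(st$events$t, 1) + round(1000 * rexp(1, 1 / cfg$gap_mean_s))
    }
    out[[si]] <- game_session(user_id, sprintf("s%02d", si), cfg$subgame,
                              strokes, device, label = label,
                              age_months = age)
  }
  out
}

#' Solve oscillation rates for a target acceleration sign-change CLES
#'
#' Under the generator's trajectory model with identical playtime
#' distributions in both groups and per-group oscillation rates `r_T`,
#' `r_D`, a session's per-axis acceleration sign-change count is
#' approximately `2 * rate * D` where `D` is the session's total stroke
#' duration, so the probability that a typical child's count exceeds a
#' disability child's is `P(log D_1 - log D_2 > log(r_D / r_T))` over
#' independent session pairs. The rate ratio is solved exactly against
#' that duration model by an internally seeded Monte Carlo evaluation of
#' the `log D` difference distribution (total duration is a sum of a
#' zero-truncated-Poisson number of lognormal stroke durations, which has
#' no closed form). This returns a [cohort_config()] with the solved
#' `oscillation_rate` contrast and everything else symmetric between
#' groups, so the sign-change contrast is the only group difference.
#'
#' @param target_cles desired probability that a typical-group count exceeds
#'   a disability-group count (0.5 < target < 1).
#' @param n_per_group children per group.
#' @param base_rate disability-group oscillation rate (cycles/second).
#' @param sdlog lognormal sdlog of stroke durations (both groups).
#' @param strokes_mean Poisson mean stroke count (both groups).
#' @param seed master seed.
#' @return a `cohort_config` with symmetric playtime/stroke parameters and
#'   the solved `oscillation_rate` contrast.
#' @export
cohort_config_for_cles <- function(target_cles, n_per_group = 200,
                                   base_rate = 2.0, sdlog = 0.5,
                                   strokes_mean = 2, seed = 1L) {
  stopifnot(target_cles > 0.5, target_cles < 1)
  # Monte Carlo model of log total session duration (isolated, fixed seed:
  # the calibration is a deterministic function of its arguments)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(260817)
  M <- 200000L
  N <- pmax(1L, rpois(M, strokes_mean))
  d <- rlnorm(sum(N), log(4), sdlog)
  logD <- log(as.numeric(rowsum(d, rep.int(seq_len(M), N))))
  half <- M %/% 2L
  z <- logD[seq_len(half)] - logD[half + seq_len(half)]
  ratio <- exp(unname(quantile(z, target_cles)))
  cohort_config(
    n_typical = n_per_group, n_disability = n_per_group,
    playtime_meanlog = c(typical = log(4), disability = log(4)),
    playtime_sdlog = c(typical = sdlog, disability = sdlog),
    strokes_per_session_mean = c(typical = strokes_mean, disability = strokes_mean),
    oscillation_amplitude = c(typical = 0.04, disability = 0.04),
    oscillation_rate = c(typical = base_rate * ratio, disability = base_rate),
    noise_sd = c(typical = 0, disability = 0),
    wander_prob = c(typical = 0, disability = 0),
    age_median = c(typical = 54, disability = 54),
    age_iqr = c(typical = 20, disability = 20),
    device_pool = list(device_info(1280, 800, 6.1)),
    gap_mean_s = 0.5,
    seed = seed)
}
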