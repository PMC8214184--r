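#' @importFrom stats median quantile rnorm runif rpois rlnorm rexp sd var
#'   setNames dpois qnorm pnorm
#' @importFrom utils head tail
NULL

SUBGAMES <- c("second", "third", "sixth")
PHASES <- c("down", "move", "up")
LABELS <- c("typical", "disability")

#' Device metadata
#'
#' Screen geometry of the tablet/phone a session was recorded on. Coordinates
#' in event logs are raw pixels; all downstream normalization divides by these
#' dimensions.
#'
#' @param width_px,height_px screen size in pixels (strictly positive).
#' @param diagonal_in physical diagonal in inches.
#' @return A `device_info` list.
#' @export
device_info <- function(width_px, height_px, diagonal_in) {
  stopifnot(width_px > 0, height_px > 0, diagonal_in > 0)
  structure(list(width_px = as.numeric(width_px),
                 height_px = as.numeric(height_px),
                 diagonal_in = as.numeric(diagonal_in)),
            class = "device_info")
}

#' Construct a stroke
#'
#' A stroke ("line") is one continuous touch: the down, move*, up trace of a
#' single drag. A tap is kept as a two-event down/up stroke; a down that never
#' received its up (app shutdown mid-drag) is closed at its last event and
#' flagged `truncated`.
#'
#' @param events data.frame with columns `t` (ms since session start,
#'   non-decreasing), `x`, `y` (pixels), `phase` (`down`/`move`/`up`).
#' @param truncated logical; stroke closed without an `up` event.
#' @return A `stroke` object.
#' @export
stroke <- function(events, truncated = FALSE) {
  stopifnot(is.data.frame(events), nrow(events) >= 1,
            all(c("t", "x", "y", "phase") %in% names(events)))
  events$t <- as.numeric(events$t)
  if (is.unsorted(events$t)) stop("stroke timestamps must be non-decreasing")
  if (events$phase[1] != "down") stop("stroke must begin with a 'down' event")
  if (!truncated && events$phase[nrow(events)] != "up")
    stop("stroke must end with an 'up' event (or be flagged truncated)")
  structure(list(events = events[, c("t", "x", "y", "phase")],
                 truncated = isTRUE(truncated)),
            class = "stroke")
}

#' Construct a game session
#'
#' One child's play of one drag-and-drop subgame: an ordered list of strokes
#' plus device geometry and (for training data) the diagnosis label and age.
#'
#' @param user_id,session_id opaque identifier strings.
#' @param subgame one of `"second"`, `"third"`, `"sixth"` (the drag-and-drop
#'   subgames; tapping subgames are out of scope).
#' @param strokes list of [stroke()] objects ordered by first-event time.
#' @param device a [device_info()].
#' @param label `"typical"`, `"disability"`, or `NA` for unlabeled data.
#' @param age_months child age in months (integer), or `NA`.
#' @return A `game_session` object.
#' @export
game_session <- function(user_id, session_id, subgame, strokes, device,
                         label = NA_character_, age_months = NA_integer_) {
  subgame <- match.arg(subgame, SUBGAMES)
  if (!is.na(label)) label <- match.arg(label, LABELS)
  stopifnot(inherits(device, "device_info"), is.list(strokes))
  if (length(strokes) > 1) {
    t0 <- vapply(strokes, function(s) s$events$t[1], numeric(1))
    if (is.unsorted(t0)) stop("strokes must be ordered by first-event time")
  }
  structure(list(user_id = as.character(user_id),
                 session_id = as.character(session_id),
                 subgame = subgame,
                 strokes = strokes,
                 device = device,
                 label = label,
                 age_months = as.integer(age_months)),
            class = "game_session")
}

#' @export
print.game_session <- function(x, ...) {
  n_ev <- sum(vapply(x$strokes, function(s) nrow(s$events), integer(1)))
  cat(sprintf("<game_session> user=%s session=%s subgame=%s: %d stroke(s), %d event(s), label=%s\n",
              x$user_id, x$session_id, x$subgame, length(x$strokes), n_ev, x$label))
  invisible(x)
}

#' Validate a session against the log-model invariants
#'
#' Checks phase bracketing, timestamp monotonicity, and coordinate bounds.
#'
#' @param session a `game_session`.
#' @return `TRUE` invisibly; stops with a message on violation.
#' @export
validate_session <- function(session) {
  stopifnot(inherits(session, "game_session"))
  dev <- session$device
  for (s in session$strokes) {
    ev <- s$events
    if (ev$phase[1] != "down") stop("stroke does not start with 'down'")
    if (!s$truncated && ev$phase[nrow(ev)] != "up")
      stop("non-truncated stroke does not end with 'up'")
    if (nrow(ev) > 2 && any(ev$phase[2:(nrow(ev) - 1)] != "move"))
      stop("interior stroke events must be 'move'")
    if (is.unsorted(ev$t)) stop("timestamps not non-decreasing within stroke")
    if (any(ev$t < 0)) stop("negative timestamp")
    if (any(ev$x < 0 | ev$x > dev$width_px) || any(ev$y < 0 | ev$y > dev$height_px))
      stop("coordinate outside device bounds")
  }
  invisible(TRUE)
}

session_key <- function(user_id, session_id, subgame)
  paste(user_id, session_id, subgame, sep = "\r")

#' Read sessions from a JSON Lines event log
#'
#' Each line of the file is one JSON record: a `"session"` header carrying
#' device geometry, label and age, or an `"event"` carrying one touch sample.
#' Events are grouped into strokes by down...up bracketing and into sessions
#' by (user, session, subgame). Events are re-sorted by timestamp within a
#' session (ties keep file order), so the format is order-insensitive.
#'
#' @param path path to a `.jsonl` event log written by [write_sessions()].
#' @param lenient if `TRUE`, orphan events (move/up before any down) are
#'   dropped with a warning instead of raising an error.
#' @return list of `game_session`, deterministically ordered by
#'   (user_id, session_id, subgame).
#' @export
read_sessions <- function(path, lenient = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(list())
  recs <- tryCatch(
    jsonlite::stream_in(textConnection(lines), verbose = FALSE),
    error = function(e) {
      # locate the offending line for a useful message
      for (i in seq_along(lines)) {
        ok <- tryCatch({ jsonlite::fromJSON(lines[i]); TRUE },
                       error = function(e2) FALSE)
        if (!ok) stop(sprintf("malformed record at line %d: %s", i,
                              substr(lines[i], 1, 60)), call. = FALSE)
      }
      stop("malformed event log: ", conditionMessage(e), call. = FALSE)
    })
  if (!"record" %in% names(recs)) stop("log records lack a 'record' field")

  hdr <- recs[recs$record == "session", , drop = FALSE]
  ev <- recs[recs$record == "event", , drop = FALSE]
  need_h <- c("user_id", "session_id", "subgame", "width_px", "height_px", "diagonal_in")
  if (nrow(hdr) && !all(need_h %in% names(hdr)))
    stop("session header missing fields: ",
         paste(setdiff(need_h, names(hdr)), collapse = ", "))
  need_e <- c("user_id", "session_id", "subgame", "t", "x", "y", "phase")
  if (nrow(ev) && !all(need_e %in% names(ev)))
    stop("event record missing fields: ",
         paste(setdiff(need_e, names(ev)), collapse = ", "))

  hkey <- session_key(hdr$user_id, hdr$session_id, hdr$subgame)
  if (anyDuplicated(hkey)) stop("duplicate session header")
  ekey <- if (nrow(ev)) session_key(ev$user_id, ev$session_id, ev$subgame) else character(0)
  unknown <- setdiff(unique(ekey), hkey)
  if (length(unknown)) stop("events reference sessions without a header record")

  # deterministic order: header records in file order
  sessions <- vector("list", nrow(hdr))
  for (i in seq_len(nrow(hdr))) {
    h <- hdr[i, ]
    k <- hkey[i]
    e <- ev[ekey == k, , drop = FALSE]
    if (nrow(e)) {
      # stable sort by t: ties keep file order
      e <- e[order(e$t), , drop = FALSE]
    }
    strokes <- bracket_strokes(e, lenient = lenient)
    sessions[[i]] <- game_session(
      user_id = h$user_id, session_id = h$session_id, subgame = h$subgame,
      strokes = strokes,
      device = device_info(h$width_px, h$height_px, h$diagonal_in),
      label = if ("label" %in% names(h) && !is.na(h$label)) h$label else NA_character_,
      age_months = if ("age_months" %in% names(h)) h$age_months else NA_integer_)
  }
  sessions
}

# Group an ordered event table into strokes by down...up bracketing.
bracket_strokes <- function(e, lenient = FALSE) {
  if (nrow(e) == 0) return(list())
  strokes <- list()
  open <- NULL
  for (i in seq_len(nrow(e))) {
    ph <- e$phase[i]
    if (ph == "down") {
      if (!is.null(open)) {
        # new down while a stroke is open: close the previous one as truncated
        strokes[[length(strokes) + 1]] <- close_stroke(e[open, , drop = FALSE], TRUE)
      }
      open <- i
    } else if (is.null(open)) {
      if (lenient) next
      stop(sprintf("orphan '%s' event at t=%s before any 'down' (use lenient = TRUE to drop)",
                   ph, format(e$t[i])))
    } else {
      open <- c(open, i)
      if (ph == "up") {
        strokes[[length(strokes) + 1]] <- close_stroke(e[open, , drop = FALSE], FALSE)
        open <- NULL
      }
    }
  }
  if (!is.null(open))  # unterminated stroke at end of log
    strokes[[length(strokes) + 1]] <- close_stroke(e[open, , drop = FALSE], TRUE)
  strokes
}

close_stroke <- function(ev, truncated) {
  rownames(ev) <- NULL
  ev <- ev[, c("t", "x", "y", "phase")]
  # JSON integers parse as integer vectors; the event model is numeric
  ev$t <- as.numeric(ev$t); ev$x <- as.numeric(ev$x); ev$y <- as.numeric(ev$y)
  stroke(ev, truncated = truncated)
}

#' Write sessions to a JSON Lines event log
#'
#' Inverse of [read_sessions()]: emits one `"session"` header line per session
#' followed by its `"event"` lines in stroke order. Round-trip identity holds
#' (`read_sessions(write_sessions(S))` reproduces `S`), timestamps are kept as
#' exact integers, and re-writing parsed output is byte-stable.
#'
#' @param sessions list of `game_session`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sessions <- function(sessions, path) {
  stopifnot(is.list(sessions))
  con <- tryCatch(file(path, open = "wt"),
                  error = function(e) stop("cannot open for writing: ", path))
  on.exit(close(con))
  for (s in sessions) {
    stopifnot(inherits(s, "game_session"))
    hdr <- list(record = "session", user_id = s$user_id,
                session_id = s$session_id, subgame = s$subgame,
                width_px = s$device$width_px, height_px = s$device$height_px,
                diagonal_in = s$device$diagonal_in)
    if (!is.na(s$label)) hdr$label <- s$label
    if (!is.na(s$age_months)) hdr$age_months <- s$age_months
    writeLines(as.character(jsonlite::toJSON(hdr, auto_unbox = TRUE, digits = NA)), con)
    ev <- session_events(s)
    if (nrow(ev)) {
      ev <- cbind(record = "event", user_id = s$user_id,
                  session_id = s$session_id, subgame = s$subgame, ev)
      jsonlite::stream_out(ev, con, verbose = FALSE, digits = NA)
    }
  }
  invisible(path)
}

#' Flatten a session's strokes into one event table
#'
#' @param session a `game_session`.
#' @return data.frame with columns `t`, `x`, `y`, `phase` over all strokes in
#'   order; zero rows for an empty session.
#' @export
session_events <- function(session) {
  if (length(session$strokes) == 0)
    return(data.frame(t = numeric(0), x = numeric(0), y = numeric(0),
                      phase = character(0)))
  do.call(rbind, lapply(session$strokes, function(s) s$events))
}

#' Export sessions as a flat CSV table
#'
#' One row per event with session metadata repeated, for spreadsheet
#' inspection. Lossy only in that the header/event distinction is flattened.
#'
#' @param sessions list of `game_session`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
export_sessions_csv <- function(sessions, path) {
  rows <- lapply(sessions, function(s) {
    ev <- session_events(s)
    if (nrow(ev) == 0) return(NULL)
    cbind(user_id = s$user_id, session_id = s$session_id, subgame = s$subgame,
          label = s$label, age_months = s$age_months,
          width_px = s$device$width_px, height_px = s$device$height_px,
          diagonal_in = s$device$diagonal_in, ev)
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) df <- data.frame()
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
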