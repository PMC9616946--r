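#' Match schedules
#'
#' A match schedule records, per session, the half intervals (verified match
#' time) and the per-player on-pitch intervals (entry/leave times, driven by
#' the starting lineup and substitutions). All intervals are closed: an
#' event exactly at a half's start or end time is inside match time.
#'
#' @param halves data frame with columns `session_id`, `half` (1 or 2),
#'   `start_s`, `end_s`; per session the halves must be non-overlapping with
#'   `start_s < end_s`.
#' @param on_pitch data frame with columns `session_id`, `player_id`,
#'   `enter_s`, `leave_s`.
#' @return An object of class `match_schedule`.
#' @export
match_schedule <- function(halves, on_pitch) {
  halves <- as.data.frame(halves, stringsAsFactors = FALSE)
  on_pitch <- as.data.frame(on_pitch, stringsAsFactors = FALSE)
  need_h <- c("session_id", "half", "start_s", "end_s")
  need_p <- c("session_id", "player_id", "enter_s", "leave_s")
  if (!all(need_h %in% names(halves)))
    stop("halves needs columns: ", paste(need_h, collapse = ", "))
  if (!all(need_p %in% names(on_pitch)))
    stop("on_pitch needs columns: ", paste(need_p, collapse = ", "))
  for (s in unique(halves$session_id)) {
    h <- halves[halves$session_id == s, ]
    h <- h[order(h$start_s), ]
    if (any(h$start_s >= h$end_s))
      stop("schedule schema error: half with start >= end in session ", s)
    if (nrow(h) > 1 && any(h$start_s[-1] <= h$end_s[-nrow(h)]))
      stop("schedule schema error: overlapping halves in session ", s)
    p <- on_pitch[on_pitch$session_id == s, ]
    if (nrow(p)) {
      if (any(p$enter_s >= p$leave_s))
        stop("schedule schema error: on-pitch interval with enter >= leave")
      if (any(p$enter_s < 0) || any(p$leave_s > max(h$end_s)))
        stop("schedule schema error: on-pitch interval outside [0, session end]")
    }
  }
  structure(list(halves = halves, on_pitch = on_pitch),
            class = "match_schedule")
}

#' @export
print.match_schedule <- function(x, ...) {
  cat("<match_schedule> ", length(unique(x$halves$session_id)),
      " session(s), ", nrow(x$halves), " half interval(s), ",
      nrow(x$on_pitch), " on-pitch interval(s)\n", sep = "")
  invisible(x)
}

#' Read and write match schedules
#'
#' On disk a schedule is a single CSV with one row per interval:
#' `session_id, kind, player_id, index, start_s, end_s`, where `kind` is
#' `"half"` (then `player_id` is empty and `index` is the half number) or
#' `"on_pitch"` (then `index` numbers the player's spells on the pitch).
#'
#' @param path file path.
#' @param schedule a [match_schedule()].
#' @return `read_schedule()` returns a [match_schedule()].
#' @export
read_schedule <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(session_id = "character",
                                       player_id = "character"))
  need <- c("session_id", "kind", "player_id", "index", "start_s", "end_s")
  if (!all(need %in% names(df)))
    stop("schedule file lacks column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  if (nrow(df) && !all(df$kind %in% c("half", "on_pitch")))
    stop("schedule schema error: kind must be 'half' or 'on_pitch'")
  h <- df[df$kind == "half", ]
  p <- df[df$kind == "on_pitch", ]
  match_schedule(
    halves = data.frame(session_id = h$session_id, half = h$index,
                        start_s = h$start_s, end_s = h$end_s,
                        stringsAsFactors = FALSE),
    on_pitch = data.frame(session_id = p$session_id, player_id = p$player_id,
                          enter_s = p$start_s, leave_s = p$end_s,
                          stringsAsFactors = FALSE)
  )
}

#' @rdname read_schedule
#' @export
write_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "match_schedule"))
  h <- schedule$halves
  p <- schedule$on_pitch
  spell <- stats::ave(seq_len(nrow(p)),
                      paste(p$session_id, p$player_id), FUN = seq_along)
  df <- rbind(
    data.frame(session_id = h$session_id, kind = "half", player_id = "",
               index = h$half, start_s = h$start_s, end_s = h$end_s,
               stringsAsFactors = FALSE),
    if (nrow(p)) data.frame(session_id = p$session_id, kind = "on_pitch",
                            player_id = p$player_id, index = spell,
                            start_s = p$enter_s, end_s = p$leave_s,
                            stringsAsFactors = FALSE)
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# is ts inside any closed half interval of its session?
in_match_time <- function(ts, session, schedule) {
  h <- schedule$halves
  vapply(seq_along(ts), function(i) {
    hi <- h[h$session_id == session[i], ]
    any(ts[i] >= hi$start_s & ts[i] <= hi$end_s)
  }, logical(1))
}

# was the player on the pitch at ts (closed intervals)?
on_pitch_at <- function(ts, player, session, schedule) {
  p <- schedule$on_pitch
  vapply(seq_along(ts), function(i) {
    pi <- p[p$session_id == session[i] & p$player_id == player[i], ]
    if (!nrow(pi)) stop("player ", player[i],
                        " absent from schedule of session ", session[i])
    any(ts[i] >= pi$enter_s & ts[i] <= pi$leave_s)
  }, logical(1))
}
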