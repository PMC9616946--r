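#' Filter sensor events to verified match time
#'
#' Removes sensor events whose timestamp falls outside every half interval
#' of their session. Intervals are closed, so an event exactly at a half's
#' start or end time is kept.
#'
#' @param events an [event_set()].
#' @param schedule a [match_schedule()] covering the events' sessions.
#' @return A list with `kept` and `removed` (both [event_set()]); the two
#'   partition the input.
#' @export
filter_match_time <- function(events, schedule) {
  stopifnot(inherits(events, "event_set"), inherits(schedule, "match_schedule"))
  unknown <- setdiff(events$meta$session_id, schedule$halves$session_id)
  if (length(unknown))
    stop("event references unknown session: ", unknown[1])
  keep <- in_match_time(events$meta$timestamp_s, events$meta$session_id,
                        schedule)
  list(kept = events[keep], removed = events[!keep])
}

#' Filter sensor events to on-pitch players
#'
#' Removes sensor events attributed to a player who was not on the pitch at
#' the event timestamp (substituted off, or not yet substituted on).
#' On-pitch intervals are closed. Every player occurring in `events` must
#' have at least one on-pitch interval in the schedule.
#'
#' @inheritParams filter_match_time
#' @return A list with `kept` and `removed` (both [event_set()]).
#' @export
filter_on_pitch <- function(events, schedule) {
  stopifnot(inherits(events, "event_set"), inherits(schedule, "match_schedule"))
  keep <- on_pitch_at(events$meta$timestamp_s, events$meta$player_id,
                      events$meta$session_id, schedule)
  list(kept = events[keep], removed = events[!keep])
}

#' Match sensor events to video-observed headers
#'
#' Assigns sensor events to video headers of the same player and session
#' within a +/- `window_s` time window (default 2 s). Multiplicity is
#' resolved by a globally greedy one-to-one assignment over candidate pairs
#' in ascending absolute time offset, with deterministic tie-breaking by
#' earlier sensor timestamp and then lexicographic event id; the result is
#' independent of input order.
#'
#' @param events an [event_set()] of already-filtered sensor events.
#' @param video_headers data frame of video header records
#'   (`header_id`, `player_id`, `session_id`, `timestamp_s`).
#' @param window_s non-negative half-width of the matching window in
#'   seconds.
#' @return A list with `assignments` (data frame `header_id`, `event_id`,
#'   `offset_s` where `offset_s` is sensor time minus video time) and
#'   `unmatched_headers` (character vector of header ids with no assigned
#'   sensor event).
#' @export
match_events <- function(events, video_headers, window_s = 2.0) {
  stopifnot(inherits(events, "event_set"))
  if (!is.numeric(window_s) || length(window_s) != 1L || window_s < 0)
    stop("window_s must be a non-negative number")
  me <- events$meta
  vh <- video_headers
  pairs <- NULL
  if (nrow(me) && nrow(vh)) {
    key_e <- paste(me$session_id, me$player_id)
    key_v <- paste(vh$session_id, vh$player_id)
    for (k in intersect(unique(key_e), unique(key_v))) {
      ei <- which(key_e == k); vi <- which(key_v == k)
      d <- outer(me$timestamp_s[ei], vh$timestamp_s[vi], `-`)
      hit <- which(abs(d) <= window_s + 1e-12, arr.ind = TRUE)
      if (nrow(hit))
        pairs <- rbind(pairs, data.frame(
          e = ei[hit[, 1]], v = vi[hit[, 2]],
          off = d[hit], stringsAsFactors = FALSE))
    }
  }
  assignments <- data.frame(header_id = character(0), event_id = character(0),
                            offset_s = numeric(0), stringsAsFactors = FALSE)
  if (!is.null(pairs) && nrow(pairs)) {
    ord <- order(abs(pairs$off), me$timestamp_s[pairs$e],
                 me$event_id[pairs$e], vh$header_id[pairs$v])
    pairs <- pairs[ord, ]
    e_used <- rep(FALSE, nrow(me)); v_used <- rep(FALSE, nrow(vh))
    for (i in seq_len(nrow(pairs))) {
      e <- pairs$e[i]; v <- pairs$v[i]
      if (!e_used[e] && !v_used[v]) {
        e_used[e] <- TRUE; v_used[v] <- TRUE
        assignments <- rbind(assignments, data.frame(
          header_id = vh$header_id[v], event_id = me$event_id[e],
          offset_s = pairs$off[i], stringsAsFactors = FALSE))
      }
    }
  }
  unmatched <- setdiff(vh$header_id, assignments$header_id)
  list(assignments = assignments, unmatched_headers = unmatched)
}

#' Build the video-verified ground truth
#'
#' Reproduces the full labelling pipeline: exclude sensor events outside
#' verified match time, exclude events of players not on the pitch, match
#' the remaining events to video-observed headers within the +/- 2 s
#' window, and label each retained event as a valid header (`VH`, matched)
#' or non-header (`NH`, unmatched). Video headers with no sensor event in
#' the window (impacts below the trigger) are dropped from the ground truth
#' and counted in the report.
#'
#' @inheritParams filter_match_time
#' @param video_log data frame of video header records.
#' @param window_s matching half-window in seconds (default 2).
#' @return A list with `labeled` (an [event_set()] of the retained events
#'   with `label`, `matched_video_id`, `match_offset_s` columns) and
#'   `report` (a `labeling_report`: raw, removed and retained counts, VH,
#'   NH, and unmatched video headers; `retained = VH + NH` and
#'   `raw = retained + removed` always hold).
#' @export
build_ground_truth <- function(events, video_log, schedule, window_s = 2.0) {
  f1 <- filter_match_time(events, schedule)
  f2 <- filter_on_pitch(f1$kept, schedule)
  kept <- f2$kept
  m <- match_events(kept, video_log, window_s)
  meta <- kept$meta
  idx <- match(meta$event_id, m$assignments$event_id)
  meta$label <- ifelse(is.na(idx), "NH", "VH")
  meta$matched_video_id <- m$assignments$header_id[idx]
  meta$match_offset_s <- m$assignments$offset_s[idx]
  labeled <- event_set(meta, kept$traces)
  report <- structure(list(
    raw = nrow(events$meta),
    removed_out_of_match = nrow(f1$removed$meta),
    removed_off_pitch = nrow(f2$removed$meta),
    retained = nrow(meta),
    vh = sum(meta$label == "VH"),
    nh = sum(meta$label == "NH"),
    unmatched_video_headers = length(m$unmatched_headers),
    video_headers = nrow(video_log)
  ), class = "labeling_report")
  stopifnot(report$retained == report$vh + report$nh,
            report$raw == report$retained + report$removed_out_of_match +
              report$removed_off_pitch)
  list(labeled = labeled, report = report)
}

#' @export
print.labeling_report <- function(x, ...) {
  cat("<labeling_report>\n",
      "  raw sensor events:        ", x$raw, "\n",
      "  removed out-of-match:     ", x$removed_out_of_match, "\n",
      "  removed off-pitch:        ", x$removed_off_pitch, "\n",
      "  retained:                 ", x$retained, "\n",
      "  valid headers (VH):       ", x$vh, "\n",
      "  non-headers (NH):         ", x$nh, "\n",
      "  unmatched video headers:  ", x$unmatched_video_headers,
      " of ", x$video_headers, "\n", sep = "")
  invisible(x)
}
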