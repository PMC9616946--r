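#' Triggered sensor event sets
#'
#' An `event_set` bundles the metadata and acceleration traces of a batch of
#' triggered sensor events. Each event is a 3-axis, 100-sample linear
#' acceleration recording in g sampled at 1000 Hz (10 ms pre-trigger, 90 ms
#' post-trigger), in axis order anterior-posterior (`ap`), left-right (`lr`),
#' inferior-superior (`is`).
#'
#' @param meta data frame with one row per event; must contain character
#'   columns `event_id`, `player_id`, `session_id` and numeric
#'   `timestamp_s` (seconds since session start, `>= 0`). Optional columns:
#'   `label` (`"VH"`/`"NH"`), `matched_video_id`, `match_offset_s`,
#'   `augmented` (logical).
#' @param traces numeric array of dimension `c(nrow(meta), 3, 100)` holding
#'   linear acceleration in g; all values must be finite.
#' @return An object of class `event_set`: a list with elements `meta` and
#'   `traces` and attribute `sample_rate_hz = 1000`.
#' @examples
#' tr <- simulate_header_trace(waveform_params(), seed = 1)
#' es <- event_set(
#'   data.frame(event_id = "e1", player_id = "p1", session_id = "s1",
#'              timestamp_s = 12.5),
#'   array(tr, c(1, 3, 100))
#' )
#' es
#' @export
event_set <- function(meta, traces) {
  stopifnot(is.data.frame(meta))
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  if (is.matrix(traces) && nrow(meta) == 1L) {
    traces <- array(traces, c(1L, dim(traces)))
  }
  x <- structure(list(meta = meta, traces = traces),
                 class = "event_set", sample_rate_hz = 1000)
  validate_event_set(x)
  x
}

AXES <- c("ap", "lr", "is")
N_SAMPLES <- 100L
N_AXES <- 3L

#' Validate an event set
#'
#' Checks the structural invariants of an [event_set()]: required metadata
#' columns, a finite `n x 3 x 100` trace array, non-negative timestamps and,
#' when a `label` column is present, the valid-header bookkeeping rules
#' (`label == "VH"` iff a matched video id is present; absolute match offset
#' at most 2 s).
#'
#' @param x object to validate.
#' @return `x`, invisibly; errors describe the first violated invariant.
#' @export
validate_event_set <- function(x) {
  if (!inherits(x, "event_set")) stop("not an event_set")
  meta <- x$meta
  need <- c("event_id", "player_id", "session_id", "timestamp_s")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop("event_set meta lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(meta$event_id)) stop("duplicated event_id")
  if (any(!is.finite(meta$timestamp_s)) || any(meta$timestamp_s < 0))
    stop("timestamp_s must be finite and >= 0")
  tr <- x$traces
  if (!is.array(tr) || length(dim(tr)) != 3L)
    stop("traces must be a 3-d array [event, axis, sample]")
  d <- dim(tr)
  if (d[1] != nrow(meta))
    stop("trace count (", d[1], ") != metadata rows (", nrow(meta), ")")
  if (d[2] != N_AXES || d[3] != N_SAMPLES)
    stop("each trace must be ", N_AXES, " axes x ", N_SAMPLES,
         " samples, got ", d[2], " x ", d[3])
  if (length(tr) && any(!is.finite(tr))) stop("non-finite acceleration value")
  if (!identical(attr(x, "sample_rate_hz"), 1000))
    stop("sample_rate_hz must be 1000")
  if ("label" %in% names(meta)) {
    if (!all(meta$label %in% c("VH", "NH"))) stop("label must be VH or NH")
    has_match <- !is.na(meta$matched_video_id)
    if (!identical(has_match, meta$label == "VH"))
      stop("label VH must coincide with a matched video id")
    off <- meta$match_offset_s[has_match]
    if (length(off) && any(abs(off) > 2 + 1e-12))
      stop("|match_offset_s| must be <= 2")
  }
  invisible(x)
}

#' @export
print.event_set <- function(x, ...) {
  n <- nrow(x$meta)
  cat("<event_set> ", n, " triggered event(s), 3 axes x 100 samples @ 1000 Hz\n",
      sep = "")
  if (n) {
    cat("  sessions: ", paste(unique(x$meta$session_id), collapse = ", "),
        "\n", sep = "")
    if ("label" %in% names(x$meta)) {
      tab <- table(factor(x$meta$label, c("VH", "NH")))
      cat("  labels:   VH ", tab[["VH"]], " / NH ", tab[["NH"]], "\n", sep = "")
    }
  }
  invisible(x)
}

#' @export
length.event_set <- function(x) nrow(x$meta)

#' Subset an event set
#'
#' @param x an [event_set()].
#' @param i integer or logical index over events.
#' @param ... unused.
#' @return An `event_set` holding the selected events.
#' @export
`[.event_set` <- function(x, i, ...) {
  meta <- x$meta[i, , drop = FALSE]
  rownames(meta) <- NULL
  structure(list(meta = meta, traces = x$traces[i, , , drop = FALSE]),
            class = "event_set", sample_rate_hz = 1000)
}

#' Combine event sets
#'
#' @param ... `event_set` objects with compatible metadata columns.
#' @return A single `event_set` with the events concatenated in order.
#' @export
combine_event_sets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1]]) && !inherits(sets[[1]], "event_set"))
    sets <- sets[[1]]
  stopifnot(length(sets) >= 1L, all(vapply(sets, inherits, TRUE, "event_set")))
  cols <- Reduce(union, lapply(sets, function(s) names(s$meta)))
  metas <- lapply(sets, function(s) {
    m <- s$meta
    for (cl in setdiff(cols, names(m))) m[[cl]] <- NA
    m[, cols, drop = FALSE]
  })
  meta <- do.call(rbind, metas)
  rownames(meta) <- NULL
  n <- nrow(meta)
  traces <- array(0, c(n, N_AXES, N_SAMPLES))
  at <- 0L
  for (s in sets) {
    k <- nrow(s$meta)
    if (k) traces[at + seq_len(k), , ] <- s$traces
    at <- at + k
  }
  event_set(meta, traces)
}

#' Peak resultant acceleration of each event
#'
#' The resultant is the per-sample Euclidean norm
#' \eqn{\sqrt{a_{ap}^2 + a_{lr}^2 + a_{is}^2}}; the peak is its maximum over
#' the 100-sample window. This is the quantity the trigger threshold and the
#' 10 g / 16 g baseline classifiers operate on.
#'
#' @param events an [event_set()].
#' @return Numeric vector of peak resultant acceleration in g, one per event.
#' @export
peak_resultant <- function(events) {
  stopifnot(inherits(events, "event_set"))
  n <- nrow(events$meta)
  if (!n) return(numeric(0))
  res <- sqrt(events$traces[, 1, , drop = FALSE]^2 +
              events$traces[, 2, , drop = FALSE]^2 +
              events$traces[, 3, , drop = FALSE]^2)
  apply(array(res, dim(res)[c(1, 3)]), 1, max)
}

# per-sample resultant of a single 3 x 100 trace matrix
trace_resultant <- function(trace) sqrt(colSums(trace^2))
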