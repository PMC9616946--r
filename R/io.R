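#' Read and write triggered sensor event tables
#'
#' Sensor events are stored one row per event in a comma-separated file with
#' metadata columns (`event_id`, `player_id`, `session_id`, `timestamp_s`)
#' followed by 300 wide acceleration columns `ap_000` ... `is_099` (axis,
#' then zero-padded sample index), in g. Optional label columns (`label`,
#' `matched_video_id`, `match_offset_s`, `augmented`) survive a round trip,
#' so the same format serves raw and labelled datasets. Acceleration is
#' serialised with 12 significant digits so downstream z-normalisation is
#' reproducible from the file alone.
#'
#' @param path file path.
#' @param events an [event_set()].
#' @return `read_sensor_events()` returns an [event_set()]; the writer
#'   returns `path` invisibly.
#' @examples
#' params <- waveform_params()
#' es <- event_set(
#'   data.frame(event_id = "e1", player_id = "p1", session_id = "s1",
#'              timestamp_s = 3.2),
#'   array(simulate_header_trace(params, seed = 2), c(1, 3, 100))
#' )
#' f <- tempfile(fileext = ".csv")
#' write_sensor_events(es, f)
#' read_sensor_events(f)
#' @export
read_sensor_events <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(event_id = "character",
                                       player_id = "character",
                                       session_id = "character"))
  trace_cols <- trace_col_names()
  miss <- setdiff(c("event_id", "player_id", "session_id", "timestamp_s"),
                  names(df))
  if (length(miss))
    stop("sensor event file lacks column(s): ", paste(miss, collapse = ", "))
  bad <- setdiff(trace_cols, names(df))
  if (length(bad))
    stop("sensor event file schema error: expected 3 axes x 100 samples, ",
         "missing column(s) such as ", bad[1])
  n <- nrow(df)
  traces <- array(0, c(n, N_AXES, N_SAMPLES))
  for (a in seq_len(N_AXES)) {
    cols <- sprintf("%s_%03d", AXES[a], 0:(N_SAMPLES - 1))
    block <- as.matrix(df[, cols, drop = FALSE])
    if (n && (!is.numeric(block) || any(!is.finite(block)))) {
      row <- which(rowSums(!is.finite(block)) > 0)[1]
      stop("parse error: non-numeric/non-finite acceleration at data line ",
           row, " (", AXES[a], " axis)")
    }
    traces[, a, ] <- block
  }
  meta <- df[, setdiff(names(df), trace_cols), drop = FALSE]
  if ("augmented" %in% names(meta)) meta$augmented <- as.logical(meta$augmented)
  if ("matched_video_id" %in% names(meta))
    meta$matched_video_id <- as.character(meta$matched_video_id)
  event_set(meta, traces)
}

trace_col_names <- function()
  as.vector(vapply(AXES, function(a) sprintf("%s_%03d", a, 0:(N_SAMPLES - 1)),
                   character(N_SAMPLES)))

#' @rdname read_sensor_events
#' @export
write_sensor_events <- function(events, path) {
  validate_event_set(events)
  meta <- events$meta
  n <- nrow(meta)
  flat <- matrix("", n, N_AXES * N_SAMPLES)
  for (a in seq_len(N_AXES)) {
    block <- matrix(events$traces[, a, ], nrow = n)
    flat[, (a - 1) * N_SAMPLES + seq_len(N_SAMPLES)] <-
      sprintf("%.12g", block)
  }
  flat <- as.data.frame(flat, stringsAsFactors = FALSE)
  names(flat) <- trace_col_names()
  out <- cbind(meta, flat)
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write sensor events to ", path)
  invisible(path)
}

#' Read and write video header logs
#'
#' A video log holds the adjudicated video-observed headers: one row per
#' header with `header_id`, `player_id`, `session_id`, `timestamp_s` and
#' `half_index` (1 or 2). When a schedule is supplied the reader checks that
#' every header timestamp lies inside the declared half interval.
#'
#' @param path file path.
#' @param log data frame of video header records.
#' @param schedule optional [match_schedule()] used to validate that each
#'   header lies inside its half.
#' @return `read_video_log()` returns a data frame of header records.
#' @export
read_video_log <- function(path, schedule = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(header_id = "character",
                                       player_id = "character",
                                       session_id = "character"))
  need <- c("header_id", "player_id", "session_id", "timestamp_s", "half_index")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("video log lacks column(s): ", paste(miss, collapse = ", "))
  if (nrow(df) && !all(df$half_index %in% c(1L, 2L)))
    stop("half_index must be 1 or 2")
  if (!is.null(schedule)) {
    for (i in seq_len(nrow(df))) {
      h <- schedule$halves
      h <- h[h$session_id == df$session_id[i] & h$half == df$half_index[i], ]
      if (!nrow(h) || df$timestamp_s[i] < h$start_s || df$timestamp_s[i] > h$end_s)
        stop("video header ", df$header_id[i], " lies outside its half interval")
    }
  }
  df
}

#' @rdname read_video_log
#' @export
write_video_log <- function(log, path) {
  utils::write.csv(log, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load a pipeline configuration file
#'
#' Reads a YAML (or JSON-compatible YAML) configuration with sections
#' `simulation`, `waveform`, `network`, `training`, `split`, `augmentation`
#' and `evaluation`. Absent keys take the documented defaults of the
#' corresponding constructors ([session_config()], [waveform_params()],
#' [network_config()], [training_config()], ...); present keys are
#' range-validated, and a violated constraint is reported with the offending
#' key name.
#'
#' @param path path to a YAML config file; an empty or absent-section file
#'   yields all defaults.
#' @return A named list with the validated configuration objects:
#'   `simulation`, `waveform`, `network`, `training`, `split`,
#'   `augmentation`, `evaluation`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  grab <- function(section) if (is.null(raw[[section]])) list() else raw[[section]]
  cfg <- list(
    simulation = do.call(session_config, grab("simulation")),
    waveform   = do.call(waveform_params, grab("waveform")),
    network    = do.call(network_config, grab("network")),
    training   = do.call(training_config, grab("training")),
    split      = do.call(split_spec, grab("split")),
    augmentation = do.call(augmentation_spec, grab("augmentation"))
  )
  ev <- grab("evaluation")
  folds <- if (is.null(ev$folds)) 5L else as.integer(ev$folds)
  if (folds < 2L) stop("config key evaluation.folds must be >= 2")
  scenario <- if (is.null(ev$scenario)) "balanced" else ev$scenario
  if (!all(scenario %in% c("balanced", "unbalanced")))
    stop("config key evaluation.scenario must be 'balanced' or 'unbalanced'")
  cfg$evaluation <- list(folds = folds, scenario = scenario)
  cfg
}

#' Split and augmentation specifications
#'
#' `split_spec()` fixes the train/validation/test fractions (defaults
#' 0.49/0.21/0.30 of the ground-truth dataset) and whether the split is
#' stratified by label. `augmentation_spec()` fixes the pink-noise
#' augmentation scale (sigma, default 10% of the per-axis trace standard
#' deviation) and the target minority/majority class ratio (default 1).
#'
#' @param fractions named numeric vector `c(train =, val =, test =)`;
#'   positive entries summing to 1.
#' @param stratify logical; stratify the split by class label.
#' @param sigma non-negative noise scale as a fraction of the per-axis
#'   standard deviation of the trace being copied.
#' @param ratio positive target VH:NH ratio after augmentation.
#' @return A list of class `split_spec` or `augmentation_spec`.
#' @export
split_spec <- function(fractions = c(train = 0.49, val = 0.21, test = 0.30),
                       stratify = TRUE) {
  fractions <- unlist(fractions)
  if (length(fractions) != 3L) stop("config key split.fractions needs 3 entries")
  if (is.null(names(fractions)) || !all(names(fractions) %in% c("train", "val", "test")))
    names(fractions) <- c("train", "val", "test")
  fractions <- fractions[c("train", "val", "test")]
  if (any(fractions < 0))
    stop("config key split.fractions: entries must be non-negative")
  if (abs(sum(fractions) - 1) > 1e-9)
    stop("config key split.fractions must sum to 1 (got ",
         format(sum(fractions)), ")")
  structure(list(fractions = fractions, stratify = isTRUE(stratify)),
            class = "split_spec")
}

#' @rdname split_spec
#' @export
augmentation_spec <- function(sigma = 0.10, ratio = 1) {
  if (!is.numeric(sigma) || sigma < 0)
    stop("config key augmentation.sigma must be >= 0")
  if (!is.numeric(ratio) || ratio <= 0)
    stop("config key augmentation.ratio must be > 0")
  structure(list(sigma = sigma, ratio = ratio), class = "augmentation_spec")
}

#' Write and read per-fold metric tables
#'
#' @param metrics data frame of metric rows (as produced by
#'   [run_scenario()]'s summaries).
#' @param path CSV path.
#' @return The reader returns the metric table as a data frame.
#' @export
write_metrics_table <- function(metrics, path) {
  utils::write.csv(metrics, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_metrics_table
#' @export
read_metrics_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
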