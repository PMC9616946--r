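#' Acceleration-threshold baseline classifier
#'
#' Labels an event a valid header whenever the peak linear acceleration
#' magnitude (per-sample resultant over the three raw, un-normalised axes)
#' exceeds `threshold_g`. The 10 g and 16 g variants are the commonly
#' applied baselines the learned classifier is compared against.
#'
#' @param events an [event_set()] of raw traces in g.
#' @param threshold_g threshold in g (strictly greater-than rule).
#' @return Character vector of `"VH"`/`"NH"` labels, one per event.
#' @examples
#' params <- waveform_params()
#' es <- event_set(
#'   data.frame(event_id = "e1", player_id = "p1", session_id = "s1",
#'              timestamp_s = 1),
#'   array(simulate_header_trace(params, seed = 1, peak = 12), c(1, 3, 100))
#' )
#' threshold_classify(es, 10)  # "VH"
#' threshold_classify(es, 16)  # "NH"
#' @export
threshold_classify <- function(events, threshold_g) {
  stopifnot(is.numeric(threshold_g), length(threshold_g) == 1L)
  ifelse(peak_resultant(events) > threshold_g, "VH", "NH")
}
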