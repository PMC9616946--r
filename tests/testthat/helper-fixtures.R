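# shared fixtures: small event sets and toy classification data, all built
# in code at test time

toy_params <- waveform_params()

# n events with traces from the generators; labels VH/NH
make_toy_data <- function(n_vh, n_nh, seed0 = 0, nh_archetype = NULL) {
  n <- n_vh + n_nh
  tr <- array(0, c(n, 3, 100))
  for (i in seq_len(n_vh))
    tr[i, , ] <- simulate_header_trace(toy_params, seed = seed0 + i)
  for (i in seq_len(n_nh))
    tr[n_vh + i, , ] <- simulate_nonheader_trace(toy_params,
                                                 seed = seed0 + 10000 + i,
                                                 archetype = nh_archetype)
  list(x = tr, y = rep(c("VH", "NH"), c(n_vh, n_nh)))
}

# small labelled event_set with synthetic traces
make_labeled_set <- function(n_vh, n_nh, seed0 = 0) {
  d <- make_toy_data(n_vh, n_nh, seed0)
  n <- n_vh + n_nh
  meta <- data.frame(
    event_id = sprintf("e%04d", seq_len(n)),
    player_id = rep(sprintf("p%02d", 1:5), length.out = n),
    session_id = "s1",
    timestamp_s = seq(10, by = 10, length.out = n),
    label = d$y,
    matched_video_id = ifelse(d$y == "VH", sprintf("h%04d", seq_len(n)), NA),
    match_offset_s = ifelse(d$y == "VH", 0.5, NA),
    stringsAsFactors = FALSE)
  event_set(meta, d$x)
}

# minimal raw (unlabelled) event set with given timestamps/players
make_raw_set <- function(timestamps, players, session = "s1", seed0 = 50) {
  n <- length(timestamps)
  tr <- array(0, c(n, 3, 100))
  for (i in seq_len(n))
    tr[i, , ] <- simulate_nonheader_trace(toy_params, seed = seed0 + i)
  event_set(data.frame(event_id = sprintf("r%03d", seq_len(n)),
                       player_id = players, session_id = session,
                       timestamp_s = timestamps, stringsAsFactors = FALSE),
            tr)
}

# two-half schedule with no substitutions: all players on for the whole match
simple_schedule <- function(players = sprintf("p%02d", 1:5),
                            session = "s1",
                            h1 = c(600, 3300), h2 = c(4200, 6900)) {
  match_schedule(
    halves = data.frame(session_id = session, half = 1:2,
                        start_s = c(h1[1], h2[1]), end_s = c(h1[2], h2[2]),
                        stringsAsFactors = FALSE),
    on_pitch = data.frame(session_id = session, player_id = players,
                          enter_s = h1[1], leave_s = h2[2],
                          stringsAsFactors = FALSE))
}

tiny_net <- network_config(n_axes = 3, n_steps = 100, hidden = 16,
                           fc_nodes = 20)

resultant <- function(trace) sqrt(colSums(trace^2))

# full width at half maximum (ms) of a sampled resultant, by linear
# interpolation of the half-maximum crossings around the peak
fwhm_ms <- function(r) {
  pk <- which.max(r)
  half <- r[pk] / 2
  left <- pk
  while (left > 1 && r[left - 1] > half) left <- left - 1
  lx <- if (left == 1) 1
        else (left - 1) + (half - r[left - 1]) / (r[left] - r[left - 1])
  right <- pk
  while (right < length(r) && r[right + 1] > half) right <- right + 1
  rx <- if (right == length(r)) right
        else right + (r[right] - half) / (r[right] - r[right + 1])
  rx - lx
}
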