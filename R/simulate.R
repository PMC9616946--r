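#' Waveform generation parameters
#'
#' Parameters of the synthetic triggered-event waveform generator. Header
#' events are single smooth raised-cosine resultant pulses whose peak
#' magnitude follows a log-normal distribution truncated to
#' `peak_range` (default median 15 g on [8, 60] g, spread set so that about
#' 6% of peaks fall in the 8-10 g band); non-headers are drawn from a
#' mixture of three structurally distinct archetypes: a narrow spike
#' (full width at half maximum under 3 ms), a damped oscillation
#' (60-150 Hz), and an irregular multi-peak burst. The acceleration is
#' distributed over the three axes by a random unit mixing vector with a
#' dominant anterior-posterior component, and white Gaussian baseline noise
#' (s.d. `noise_sd` g per axis) fills the samples outside the pulse support.
#'
#' @param peak_meanlog,peak_sdlog log-normal parameters of the header peak
#'   resultant magnitude (g).
#' @param peak_range truncation bounds (g) for header peaks; the lower bound
#'   is the trigger threshold.
#' @param duration_ms_range uniform range of the header pulse duration (ms).
#' @param archetype_weights non-negative mixture weights for the non-header
#'   archetypes `spike`, `ringing`, `multi`; normalised to sum to 1.
#' @param spike_meanlog,spike_sdlog,spike_range peak-magnitude distribution
#'   of the spike archetype; the lower truncation stays at or above 11 g so
#'   the sub-3 ms width is geometrically attainable above the 8 g trigger.
#' @param ringing_meanlog,ringing_sdlog,ringing_range initial amplitude
#'   distribution of the damped oscillation (g).
#' @param ringing_freq_range oscillation frequency range (Hz).
#' @param ringing_tau_ms_range exponential decay time-constant range (ms).
#' @param multi_range amplitude range (g) of the leading lump of the
#'   multi-peak archetype.
#' @param ap_weight_range range of the anterior-posterior share of the axis
#'   mixing vector before normalisation.
#' @param noise_sd baseline white-noise standard deviation per axis (g).
#' @return A validated list of class `waveform_params`.
#' @export
waveform_params <- function(peak_meanlog = log(15), peak_sdlog = 0.28,
                            peak_range = c(8, 60),
                            duration_ms_range = c(8, 16),
                            archetype_weights = c(spike = 0.45,
                                                  ringing = 0.35,
                                                  multi = 0.20),
                            spike_meanlog = log(16), spike_sdlog = 0.35,
                            spike_range = c(11, 80),
                            ringing_meanlog = log(10), ringing_sdlog = 0.3,
                            ringing_range = c(8.3, 30),
                            ringing_freq_range = c(60, 150),
                            ringing_tau_ms_range = c(15, 35),
                            multi_range = c(8.5, 25),
                            ap_weight_range = c(0.75, 0.95),
                            noise_sd = 0.3) {
  aw <- unlist(archetype_weights)
  if (length(aw) != 3L) stop("archetype_weights needs 3 entries")
  if (is.null(names(aw)) || !all(c("spike", "ringing", "multi") %in% names(aw)))
    names(aw) <- c("spike", "ringing", "multi")
  if (any(aw < 0) || sum(aw) <= 0)
    stop("archetype_weights must be non-negative with positive sum")
  aw <- aw[c("spike", "ringing", "multi")] / sum(aw)
  ordered2 <- function(r, nm) {
    if (length(r) != 2L || r[1] >= r[2]) stop(nm, " bounds must be ordered")
    as.numeric(r)
  }
  p <- list(
    peak_meanlog = peak_meanlog, peak_sdlog = peak_sdlog,
    peak_range = ordered2(peak_range, "peak_range"),
    duration_ms_range = ordered2(duration_ms_range, "duration_ms_range"),
    archetype_weights = aw,
    spike_meanlog = spike_meanlog, spike_sdlog = spike_sdlog,
    spike_range = ordered2(spike_range, "spike_range"),
    ringing_meanlog = ringing_meanlog, ringing_sdlog = ringing_sdlog,
    ringing_range = ordered2(ringing_range, "ringing_range"),
    ringing_freq_range = ordered2(ringing_freq_range, "ringing_freq_range"),
    ringing_tau_ms_range = ordered2(ringing_tau_ms_range, "ringing_tau_ms_range"),
    multi_range = ordered2(multi_range, "multi_range"),
    ap_weight_range = ordered2(ap_weight_range, "ap_weight_range"),
    noise_sd = as.numeric(noise_sd)
  )
  if (p$noise_sd < 0) stop("noise_sd must be >= 0")
  if (p$spike_range[1] < 11)
    stop("spike_range lower bound must be >= 11 g (sub-3 ms width constraint)")
  structure(p, class = "waveform_params")
}

# Evaluate seed handling without clobbering the caller's RNG stream when a
# seed is given; with seed = NULL the current stream is consumed.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", globalenv())
  on.exit(if (has) assign(".Random.seed", old, globalenv())
          else rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

rlnorm_trunc <- function(n, meanlog, sdlog, lo, hi) {
  plo <- stats::plnorm(lo, meanlog, sdlog)
  phi <- stats::plnorm(hi, meanlog, sdlog)
  stats::qlnorm(plo + stats::runif(n) * (phi - plo), meanlog, sdlog)
}

# closed-form mass of the truncated header-peak distribution on [a, b)
truncated_peak_mass <- function(params, a, b) {
  lo <- params$peak_range[1]; hi <- params$peak_range[2]
  pl <- function(q) stats::plnorm(q, params$peak_meanlog, params$peak_sdlog)
  (pl(min(max(b, lo), hi)) - pl(min(max(a, lo), hi))) / (pl(hi) - pl(lo))
}

# random unit axis-mixing vector with dominant anterior-posterior component
axis_mixing <- function(params) {
  ap <- stats::runif(1, params$ap_weight_range[1], params$ap_weight_range[2])
  rest <- sqrt(max(0, 1 - ap^2))
  phi <- stats::runif(1, 0, 2 * pi)
  u <- c(ap, rest * cos(phi), rest * sin(phi))
  u / sqrt(sum(u^2))
}

TRIGGER_INDEX <- 11L  # 1-based sample index of the trigger (0-based index 10)

# Discrete raised-cosine resultant envelope that crosses `trigger` exactly at
# the trigger sample and attains `peak` exactly at a sample `rise` ms later.
# Returns the 100-sample envelope (g).
rc_envelope <- function(peak, trigger, rise_ms) {
  stopifnot(peak > trigger, rise_ms >= 1)
  # cross a hair above the threshold so roundoff cannot land below it
  trigger <- trigger * (1 + 1e-9)
  frac <- acos(1 - 2 * trigger / peak) / (2 * pi)  # crossing position / duration
  dur <- rise_ms / (0.5 - frac)                    # ms; peak at s = dur/2
  s_star <- frac * dur
  s <- (0:(N_SAMPLES - 1) - (TRIGGER_INDEX - 1)) + s_star  # ms along pulse
  h <- ifelse(s >= 0 & s <= dur, peak / 2 * (1 - cos(2 * pi * s / dur)), 0)
  h
}

# baseline noise confined to samples where the envelope is (near) zero
add_baseline_noise <- function(signal3, envelope, noise_sd) {
  mask <- envelope < 1e-9
  if (any(mask) && noise_sd > 0) {
    k <- sum(mask)
    signal3[, mask] <- signal3[, mask] +
      matrix(stats::rnorm(3 * k, 0, noise_sd), 3, k)
  }
  signal3
}

#' Simulate a triggered header trace
#'
#' Generates one synthetic 3-axis, 100-sample header event: a single smooth
#' raised-cosine resultant pulse whose peak magnitude is drawn from the
#' truncated log-normal of `params`. The discrete envelope is constructed so
#' that the resultant first reaches the trigger threshold exactly at sample
#' index 10 (0-based; 10 ms pre-trigger) and attains the drawn peak exactly
#' at a later sample, emulating the sensor's trigger semantics. Samples
#' outside the pulse support carry only baseline noise.
#'
#' @param params a [waveform_params()].
#' @param seed optional integer seed for reproducible draws.
#' @param trigger_g trigger threshold in g (default 8).
#' @param peak optional fixed peak magnitude (g) overriding the random draw;
#'   must exceed `trigger_g`.
#' @return A `3 x 100` numeric matrix (rows `ap`, `lr`, `is`) in g.
#' @examples
#' tr <- simulate_header_trace(waveform_params(), seed = 1)
#' max(sqrt(colSums(tr^2)))  # peak resultant in g
#' @export
simulate_header_trace <- function(params, seed = NULL, trigger_g = 8,
                                  peak = NULL) {
  stopifnot(inherits(params, "waveform_params"))
  with_seed(seed, {
    if (is.null(peak))
      peak <- rlnorm_trunc(1, params$peak_meanlog, params$peak_sdlog,
                           params$peak_range[1], params$peak_range[2])
    peak <- max(peak, trigger_g * 1.02)  # degenerate-at-trigger guard
    dur <- stats::runif(1, params$duration_ms_range[1],
                        params$duration_ms_range[2])
    frac <- acos(1 - 2 * trigger_g / peak) / (2 * pi)
    rise <- max(1, round(dur * (0.5 - frac)))
    h <- rc_envelope(peak, trigger_g, rise)
    u <- axis_mixing(params)
    tr <- outer(u, h)
    tr <- add_baseline_noise(tr, h, params$noise_sd)
    rownames(tr) <- AXES
    tr
  })
}

#' Simulate a triggered non-header trace
#'
#' Generates one spurious triggered event from a mixture of three
#' archetypes, all structurally distinct from the smooth header pulse:
#' \describe{
#'   \item{`spike`}{a very narrow raised-cosine transient with resultant
#'     full-width-at-half-maximum below 3 ms;}
#'   \item{`ringing`}{an exponentially damped 60-150 Hz oscillation on the
#'     dominant axis;}
#'   \item{`multi`}{2-4 irregular raised-cosine lumps of varying amplitude.}
#' }
#' Every archetype obeys the same trigger alignment contract as headers:
#' the resultant first reaches the trigger threshold at sample index 10
#' (0-based) and samples 0-9 contain only baseline noise.
#'
#' @inheritParams simulate_header_trace
#' @param archetype one of `"spike"`, `"ringing"`, `"multi"`, or `NULL` to
#'   draw from `params$archetype_weights`.
#' @return A `3 x 100` numeric matrix (rows `ap`, `lr`, `is`) in g.
#' @export
simulate_nonheader_trace <- function(params, seed = NULL, trigger_g = 8,
                                     archetype = NULL) {
  stopifnot(inherits(params, "waveform_params"))
  with_seed(seed, {
    if (is.null(archetype))
      archetype <- sample(names(params$archetype_weights), 1,
                          prob = params$archetype_weights)
    archetype <- match.arg(archetype, c("spike", "ringing", "multi"))
    u <- axis_mixing(params)
    idx0 <- TRIGGER_INDEX  # 1-based trigger sample
    if (archetype == "spike") {
      peak <- rlnorm_trunc(1, params$spike_meanlog, params$spike_sdlog,
                           params$spike_range[1], params$spike_range[2])
      h <- rc_envelope(peak, trigger_g, rise_ms = 1)
      tr <- outer(u, h)
      tr <- add_baseline_noise(tr, h, params$noise_sd)
    } else if (archetype == "ringing") {
      amp <- rlnorm_trunc(1, params$ringing_meanlog, params$ringing_sdlog,
                          params$ringing_range[1], params$ringing_range[2])
      f <- stats::runif(1, params$ringing_freq_range[1],
                        params$ringing_freq_range[2])
      tau <- stats::runif(1, params$ringing_tau_ms_range[1],
                          params$ringing_tau_ms_range[2])
      s <- (0:(N_SAMPLES - 1)) - (idx0 - 1)             # ms relative to trigger
      sig <- ifelse(s >= 0, amp * exp(-s / tau) * cos(2 * pi * f * s / 1000), 0)
      tr <- outer(u, sig)
      if (params$noise_sd > 0) {
        noise <- matrix(stats::rnorm(3 * N_SAMPLES, 0, params$noise_sd),
                        3, N_SAMPLES)
        noise[, idx0] <- 0  # trigger-sample resultant stays at `amp` exactly
        tr <- tr + noise
      }
    } else {
      peak1 <- stats::runif(1, params$multi_range[1], params$multi_range[2])
      h <- rc_envelope(peak1, trigger_g, rise_ms = 1)
      n_extra <- sample(1:3, 1)
      for (k in seq_len(n_extra)) {
        centre <- stats::runif(1, 20, 85)                 # ms after window start
        dur <- stats::runif(1, 2, 5)  # narrow transients, unlike header pulses
        amp <- peak1 * stats::runif(1, 0.4, 1.0)
        s <- (0:(N_SAMPLES - 1)) - centre + dur / 2
        h <- h + ifelse(s >= 0 & s <= dur,
                        amp / 2 * (1 - cos(2 * pi * s / dur)), 0)
      }
      tr <- outer(u, h)
      tr <- add_baseline_noise(tr, h, params$noise_sd)
    }
    rownames(tr) <- AXES
    tr
  })
}

#' Session simulation configuration
#'
#' Describes one synthetic match session: the roster, half lengths and
#' substitution count (which induce the per-player on-pitch intervals), the
#' number of true headers, the sensor miss rate (headers whose impact stays
#' below the trigger so no sensor event exists), the spurious-event load and
#' the sensor-video timestamp jitter. The session timeline places 600 s of
#' pre-match and post-match time and a 900 s half-time break around two
#' halves, so out-of-match triggers have somewhere to live.
#'
#' @param session_id session identifier.
#' @param n_players roster size; `n_on_pitch` of them start.
#' @param n_on_pitch players simultaneously on the pitch (default 11).
#' @param half_length_s half duration in seconds (default 2700).
#' @param n_substitutions substitutions in the second half; bench size
#'   `n_players - n_on_pitch` must cover them.
#' @param n_headers true header events in the session (default 39, the
#'   per-match mean implied by 1016 headers over 26 matches).
#' @param miss_rate probability that a true header triggers no sensor event
#'   (default 0.11, reproducing an 89% capture rate).
#' @param nh_per_vh in-match on-pitch spurious events per sensor-captured
#'   header (default 21, the observed class imbalance after filtering).
#' @param n_out_of_match spurious triggers outside verified match time.
#' @param n_off_pitch spurious triggers during match time from players not
#'   on the pitch (requires at least one substitution).
#' @param trigger_g trigger threshold in g (default 8).
#' @param jitter_sd_s standard deviation (s) of the sensor-video timestamp
#'   jitter; draws are truncated to `(-jitter_max_s, jitter_max_s)`.
#' @param jitter_max_s truncation bound, strictly below the 2 s matching
#'   window so matching is recoverable by construction (default 1.9).
#' @param min_separation_s minimum spacing between a player's header and any
#'   other scheduled event of the same player (default 4 s), which makes the
#'   +/- 2 s matching unambiguous on synthetic truth.
#' @return A validated list of class `session_config`.
#' @export
session_config <- function(session_id = "s1", n_players = 14, n_on_pitch = 11,
                           half_length_s = 2700, n_substitutions = 3,
                           n_headers = 39, miss_rate = 0.11, nh_per_vh = 21,
                           n_out_of_match = 600, n_off_pitch = 340,
                           trigger_g = 8, jitter_sd_s = 0.5,
                           jitter_max_s = 1.9, min_separation_s = 4) {
  cfg <- list(session_id = as.character(session_id),
              n_players = as.integer(n_players),
              n_on_pitch = as.integer(n_on_pitch),
              half_length_s = as.numeric(half_length_s),
              n_substitutions = as.integer(n_substitutions),
              n_headers = as.integer(n_headers),
              miss_rate = as.numeric(miss_rate),
              nh_per_vh = as.numeric(nh_per_vh),
              n_out_of_match = as.integer(n_out_of_match),
              n_off_pitch = as.integer(n_off_pitch),
              trigger_g = as.numeric(trigger_g),
              jitter_sd_s = as.numeric(jitter_sd_s),
              jitter_max_s = as.numeric(jitter_max_s),
              min_separation_s = as.numeric(min_separation_s))
  if (cfg$n_on_pitch > cfg$n_players)
    stop("configuration error: more simultaneous players than roster")
  if (cfg$n_substitutions > cfg$n_players - cfg$n_on_pitch)
    stop("configuration error: bench too small for n_substitutions")
  if (cfg$miss_rate < 0 || cfg$miss_rate >= 1)
    stop("config key miss_rate must be in [0, 1)")
  if (cfg$nh_per_vh <= 0) stop("config key nh_per_vh must be > 0")
  if (cfg$jitter_max_s >= 2 || cfg$jitter_max_s <= 0)
    stop("config key jitter_max_s must lie in (0, 2)")
  if (cfg$n_off_pitch > 0 && cfg$n_substitutions < 1)
    stop("configuration error: off-pitch events need at least 1 substitution")
  if (cfg$half_length_s <= 60) stop("config key half_length_s too short")
  if (cfg$n_headers < 0) stop("config key n_headers must be >= 0")
  structure(cfg, class = "session_config")
}

#' Simulate a full match session
#'
#' Emits everything downstream stages consume: the triggered sensor events
#' (headers that exceeded the trigger, plus in-match, out-of-match and
#' off-pitch spurious events), the adjudicated video header log, the match
#' schedule, and a truth table recording the intended label of every sensor
#' event. True headers produce one video record each and - unless missed at
#' the configured `miss_rate` - one sensor record whose timestamp carries
#' truncated-Gaussian jitter strictly inside the +/- 2 s matching window.
#' Spurious events of a player are kept at least `min_separation_s` away
#' from that player's header times, so time-window matching against the
#' video log recovers the truth table exactly.
#'
#' @param cfg a [session_config()].
#' @param params a [waveform_params()].
#' @param seed integer seed; identical seed and configuration give
#'   bit-identical output.
#' @return A list with components `events` ([event_set()]), `video` (data
#'   frame of video header records), `schedule` ([match_schedule()]) and
#'   `truth` (data frame: `event_id`, `category`, `true_label`,
#'   `header_id`).
#' @export
simulate_session <- function(cfg, params = waveform_params(), seed = 1) {
  stopifnot(inherits(cfg, "session_config"), inherits(params, "waveform_params"))
  with_seed(seed, {
    L <- cfg$half_length_s
    pre <- 600; brk <- 900; post <- 600
    h1 <- c(pre, pre + L); h2 <- c(pre + L + brk, pre + 2 * L + brk)
    session_end <- h2[2] + post
    players <- sprintf("p%02d", seq_len(cfg$n_players))
    starters <- players[seq_len(cfg$n_on_pitch)]
    bench <- setdiff(players, starters)

    # substitutions: in the second half, a starter leaves, a bench player enters
    on_pitch <- data.frame(session_id = cfg$session_id, player_id = starters,
                           enter_s = h1[1], leave_s = h2[2],
                           stringsAsFactors = FALSE)
    if (cfg$n_substitutions > 0) {
      t_subs <- sort(stats::runif(cfg$n_substitutions, h2[1] + 60, h2[2] - 60))
      leaving <- sample(starters, cfg$n_substitutions)
      entering <- bench[seq_len(cfg$n_substitutions)]
      for (k in seq_len(cfg$n_substitutions)) {
        on_pitch$leave_s[on_pitch$player_id == leaving[k]] <- t_subs[k]
        on_pitch <- rbind(on_pitch,
                          data.frame(session_id = cfg$session_id,
                                     player_id = entering[k],
                                     enter_s = t_subs[k], leave_s = h2[2],
                                     stringsAsFactors = FALSE))
      }
    }
    schedule <- match_schedule(
      halves = data.frame(session_id = cfg$session_id, half = 1:2,
                          start_s = c(h1[1], h2[1]), end_s = c(h1[2], h2[2]),
                          stringsAsFactors = FALSE),
      on_pitch = on_pitch)

    pitch_players_at <- function(t) {
      on_pitch$player_id[t >= on_pitch$enter_s & t <= on_pitch$leave_s]
    }
    rand_match_time <- function() {
      u <- stats::runif(1, 0, 2 * L)
      if (u < L) h1[1] + u else h2[1] + (u - L)
    }

    # schedule headers: uniform match times, player on pitch, >= min_sep apart
    header_times <- numeric(0); header_players <- character(0)
    busy <- stats::setNames(vector("list", length(players)), players)
    place <- function(avoid_margin) {
      for (try in 1:10000) {
        t <- rand_match_time()
        cand <- pitch_players_at(t)
        if (!length(cand)) next
        p <- if (length(cand) == 1L) cand else sample(cand, 1)
        if (!length(busy[[p]]) || min(abs(busy[[p]] - t)) >= avoid_margin)
          return(list(t = t, p = p))
      }
      stop("configuration error: could not place event with required separation")
    }
    for (i in seq_len(cfg$n_headers)) {
      pl <- place(cfg$min_separation_s)
      header_times <- c(header_times, pl$t)
      header_players <- c(header_players, pl$p)
      busy[[pl$p]] <- c(busy[[pl$p]], pl$t)
    }
    ord <- order(header_times)
    header_times <- header_times[ord]; header_players <- header_players[ord]
    n_h <- length(header_times)
    header_ids <- sprintf("h%04d", seq_len(n_h))
    video <- data.frame(header_id = header_ids, player_id = header_players,
                        session_id = cfg$session_id, timestamp_s = header_times,
                        half_index = ifelse(header_times <= h1[2], 1L, 2L),
                        stringsAsFactors = FALSE)

    captured <- if (n_h) stats::runif(n_h) >= cfg$miss_rate else logical(0)
    jitter <- vapply(seq_len(n_h), function(i) {
      repeat {
        j <- stats::rnorm(1, 0, cfg$jitter_sd_s)
        if (abs(j) <= cfg$jitter_max_s) return(j)
      }
    }, numeric(1))

    rec <- list()  # per sensor event: timestamp, player, category, header_id
    for (i in which(captured))
      rec[[length(rec) + 1]] <- list(t = header_times[i] + jitter[i],
                                     p = header_players[i],
                                     cat = "header", hid = header_ids[i])
    n_nh <- round(cfg$nh_per_vh * sum(captured))
    for (i in seq_len(n_nh)) {
      # keep spurious events of a player out of the matching window of that
      # player's headers (min_separation margin), so the truth table stays
      # recoverable by time-window matching
      repeat {
        pl <- place(0)
        ht <- header_times[header_players == pl$p]
        if (!length(ht) || min(abs(ht - pl$t)) >= cfg$min_separation_s) break
      }
      rec[[length(rec) + 1]] <- list(t = pl$t, p = pl$p,
                                     cat = "spurious_in_match", hid = NA)
    }
    if (cfg$n_out_of_match > 0) {
      segs <- rbind(c(0, h1[1]), c(h1[2], h2[1]), c(h2[2], session_end))
      lens <- segs[, 2] - segs[, 1]
      for (i in seq_len(cfg$n_out_of_match)) {
        k <- sample(3, 1, prob = lens)
        t <- stats::runif(1, segs[k, 1], segs[k, 2])
        rec[[length(rec) + 1]] <- list(t = t, p = sample(players, 1),
                                       cat = "spurious_out_of_match", hid = NA)
      }
    }
    if (cfg$n_off_pitch > 0) {
      # feasible (player, interval): match time minus the player's pitch time
      gaps <- list()
      for (p in unique(on_pitch$player_id)) {
        iv <- on_pitch[on_pitch$player_id == p, ]
        for (half in list(h1, h2)) {
          cov <- iv[iv$enter_s < half[2] & iv$leave_s > half[1], ]
          pts <- sort(unique(c(half, pmax(pmin(c(cov$enter_s, cov$leave_s),
                                               half[2]), half[1]))))
          for (j in seq_len(length(pts) - 1)) {
            mid <- (pts[j] + pts[j + 1]) / 2
            on <- any(mid >= iv$enter_s & mid <= iv$leave_s)
            if (!on && pts[j + 1] - pts[j] > 2)
              gaps[[length(gaps) + 1]] <- list(p = p, a = pts[j] + 1,
                                               b = pts[j + 1] - 1)
          }
        }
      }
      if (!length(gaps))
        stop("configuration error: no off-pitch match time available")
      glen <- vapply(gaps, function(g) g$b - g$a, numeric(1))
      for (i in seq_len(cfg$n_off_pitch)) {
        repeat {
          g <- gaps[[sample(length(gaps), 1, prob = glen)]]
          t <- stats::runif(1, g$a, g$b)
          ht <- header_times[header_players == g$p]
          if (!length(ht) || min(abs(ht - t)) >= cfg$min_separation_s) break
        }
        rec[[length(rec) + 1]] <- list(t = t, p = g$p,
                                       cat = "spurious_off_pitch", hid = NA)
      }
    }

    n_ev <- length(rec)
    ts <- vapply(rec, `[[`, numeric(1), "t")
    ord <- order(ts)
    rec <- rec[ord]; ts <- ts[ord]
    traces <- array(0, c(n_ev, N_AXES, N_SAMPLES))
    for (i in seq_len(n_ev))
      traces[i, , ] <- if (rec[[i]]$cat == "header")
        simulate_header_trace(params, trigger_g = cfg$trigger_g)
      else
        simulate_nonheader_trace(params, trigger_g = cfg$trigger_g)
    meta <- data.frame(
      event_id = sprintf("e%05d", seq_len(n_ev)),
      player_id = vapply(rec, `[[`, character(1), "p"),
      session_id = cfg$session_id, timestamp_s = ts,
      stringsAsFactors = FALSE)
    truth <- data.frame(
      event_id = meta$event_id,
      category = vapply(rec, `[[`, character(1), "cat"),
      true_label = ifelse(vapply(rec, `[[`, character(1), "cat") == "header",
                          "VH", "NH"),
      header_id = vapply(rec, function(r) as.character(r$hid), character(1)),
      stringsAsFactors = FALSE)
    list(events = event_set(meta, traces), video = video,
         schedule = schedule, truth = truth)
  })
}
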