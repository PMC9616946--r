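test_that("match-time filtering uses closed half intervals", {
  sched <- simple_schedule()  # halves [600,3300] and [4200,6900]
  es <- make_raw_set(timestamps = c(600, 3300, 3500, 4200, 7000, 100),
                     players = rep("p01", 6))
  out <- filter_match_time(es, sched)
  expect_equal(out$kept$meta$event_id, es$meta$event_id[c(1, 2, 4)])
  expect_equal(out$removed$meta$event_id, es$meta$event_id[c(3, 5, 6)])
  # partition is exhaustive and disjoint
  expect_setequal(c(out$kept$meta$event_id, out$removed$meta$event_id),
                  es$meta$event_id)
  expect_error(filter_match_time(
    make_raw_set(1000, "p01", session = "mystery"), sched), "unknown session")
})

test_that("on-pitch filtering respects substitution intervals", {
  sched <- match_schedule(
    halves = data.frame(session_id = "s1", half = 1:2,
                        start_s = c(600, 4200), end_s = c(3300, 6900)),
    on_pitch = data.frame(session_id = "s1",
                          player_id = c("p01", "p02"),
                          enter_s = c(600, 5000), leave_s = c(5000, 6900)))
  es <- make_raw_set(timestamps = c(4800, 5010, 4800),
                     players = c("p01", "p01", "p02"))
  out <- filter_on_pitch(es, sched)
  expect_equal(out$kept$meta$event_id, es$meta$event_id[1])   # before sub-off
  expect_equal(out$removed$meta$event_id, es$meta$event_id[2:3])
  expect_error(filter_on_pitch(make_raw_set(700, "p99"), sched),
               "absent from schedule")
})

test_that("time-window matching follows the minimum-offset rule", {
  vh <- data.frame(header_id = "h1", player_id = "p01", session_id = "s1",
                   timestamp_s = 1000, stringsAsFactors = FALSE)
  # one candidate 1.9 s after the header -> assigned
  m <- match_events(make_raw_set(1001.9, "p01"), vh)
  expect_equal(m$assignments$event_id, "r001")
  expect_equal(m$assignments$offset_s, 1.9)
  # only candidate 2.5 s away -> header unmatched
  m2 <- match_events(make_raw_set(1002.5, "p01"), vh)
  expect_equal(nrow(m2$assignments), 0L)
  expect_equal(m2$unmatched_headers, "h1")
  # two candidates at +0.3 and -1.0 -> the closer one wins
  m3 <- match_events(make_raw_set(c(1000.3, 999.0), c("p01", "p01")), vh)
  expect_equal(m3$assignments$event_id, "r001")
  expect_equal(m3$assignments$offset_s, 0.3)
  # a different player's event never matches
  m4 <- match_events(make_raw_set(1000.1, "p02"), vh)
  expect_equal(m4$unmatched_headers, "h1")
  expect_error(match_events(make_raw_set(1000, "p01"), vh, window_s = -1),
               "non-negative")
})

test_that("matching is one-to-one and independent of input order", {
  vh <- data.frame(header_id = c("h1", "h2"), player_id = "p01",
                   session_id = "s1", timestamp_s = c(1000, 1003),
                   stringsAsFactors = FALSE)
  es <- make_raw_set(c(1001.2, 1002.4), c("p01", "p01"))
  m <- match_events(es, vh)
  # each event to at most one header: r001->h1 (1.2) then r002->h2 (0.6)
  expect_equal(sort(m$assignments$event_id), c("r001", "r002"))
  expect_equal(m$assignments$header_id[m$assignments$event_id == "r002"], "h2")
  for (perm in list(2:1, 1:2)) {
    mp <- match_events(es[perm], vh[2:1, ])
    expect_equal(mp$assignments[order(mp$assignments$event_id), ]$header_id,
                 m$assignments[order(m$assignments$event_id), ]$header_id)
  }
})

test_that("greedy matching equals exhaustive matching on sparse instances", {
  # events >= 5 s apart: every header has at most one in-window candidate,
  # where the greedy rule and exhaustive enumeration coincide
  for (s in 1:10) {
    set.seed(s)
    n_h <- 4
    ht <- sort(runif(n_h, 100, 900)) * 10       # widely separated
    vh <- data.frame(header_id = sprintf("h%d", 1:n_h), player_id = "p01",
                     session_id = "s1", timestamp_s = ht,
                     stringsAsFactors = FALSE)
    evt <- ht + runif(n_h, -3, 3)               # some inside, some outside
    es <- make_raw_set(evt, rep("p01", n_h))
    m <- match_events(es, vh)
    # brute force: per header the unique candidate within the window
    expected <- 0L
    for (i in seq_len(n_h)) {
      d <- abs(evt - ht[i])
      if (min(d) <= 2) expected <- expected + 1L
    }
    expect_equal(nrow(m$assignments), expected)
    if (nrow(m$assignments))
      expect_true(all(abs(m$assignments$offset_s) <= 2))
  }
})

test_that("ground-truth bookkeeping conserves counts against the truth table", {
  cfg <- session_config(n_headers = 40, n_out_of_match = 60, n_off_pitch = 30)
  sim <- simulate_session(cfg, toy_params, seed = 21)
  gt <- build_ground_truth(sim$events, sim$video, sim$schedule)
  r <- gt$report
  expect_equal(r$raw, length(sim$events))
  expect_equal(r$retained, r$vh + r$nh)
  expect_equal(r$raw, r$retained + r$removed_out_of_match + r$removed_off_pitch)
  expect_equal(r$removed_out_of_match,
               sum(sim$truth$category == "spurious_out_of_match"))
  expect_equal(r$removed_off_pitch,
               sum(sim$truth$category == "spurious_off_pitch"))
  # labels agree with the simulator's intent
  tt <- sim$truth[match(gt$labeled$meta$event_id, sim$truth$event_id), ]
  expect_equal(gt$labeled$meta$label, tt$true_label)
})

test_that("with no video headers every retained event is a non-header", {
  cfg <- session_config(n_headers = 5, n_out_of_match = 10, n_off_pitch = 0)
  sim <- simulate_session(cfg, toy_params, seed = 31)
  empty_video <- sim$video[integer(0), ]
  gt <- build_ground_truth(sim$events, empty_video, sim$schedule)
  expect_true(all(gt$labeled$meta$label == "NH"))
  expect_equal(gt$report$vh, 0L)
})

test_that("shrinking the window never increases the match count", {
  cfg <- session_config(n_headers = 30, n_out_of_match = 0, n_off_pitch = 0)
  sim <- simulate_session(cfg, toy_params, seed = 41)
  f <- filter_match_time(sim$events, sim$schedule)$kept
  prev <- Inf
  for (w in c(2, 1, 0.5, 0.1, 0)) {
    n <- nrow(match_events(f, sim$video, window_s = w)$assignments)
    expect_lte(n, prev)
    prev <- n
  }
})
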