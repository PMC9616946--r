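test_that("header traces honour the trigger alignment contract", {
  for (s in 1:40) {
    tr <- simulate_header_trace(toy_params, seed = s)
    r <- resultant(tr)
    expect_gte(r[11], 8)            # 0-based index 10: first trigger crossing
    expect_lt(max(r[1:10]), 8)      # pre-trigger samples: baseline only
  }
  expect_identical(simulate_header_trace(toy_params, seed = 3),
                   simulate_header_trace(toy_params, seed = 3))
})

test_that("a degenerate peak distribution is reproduced at the peak sample", {
  for (s in 1:10) {
    tr <- simulate_header_trace(toy_params, seed = s, peak = 20)
    expect_true(abs(max(resultant(tr)) - 20) <= 0.2)  # within 1%
  }
})

test_that("the low-magnitude header fraction matches the closed-form mass", {
  n <- 1000
  peaks <- vapply(seq_len(n), function(s)
    max(resultant(simulate_header_trace(toy_params, seed = s))), numeric(1))
  emp <- mean(peaks >= 8 & peaks < 10)
  mass <- headrec:::truncated_peak_mass(toy_params, 8, 10)
  halfwidth <- 1.96 * sqrt(mass * (1 - mass) / n)
  expect_lt(abs(emp - mass), halfwidth + 0.005)
})

test_that("the spike archetype is a sub-3-ms transient", {
  for (s in 1:20) {
    tr <- simulate_nonheader_trace(toy_params, seed = s, archetype = "spike")
    expect_lt(fwhm_ms(resultant(tr)), 3)
  }
})

test_that("the ringing archetype oscillates after the trigger", {
  for (s in 1:20) {
    tr <- simulate_nonheader_trace(toy_params, seed = s, archetype = "ringing")
    dom <- which.max(abs(tr[, 11]))
    d <- diff(tr[dom, 11:51])            # 40 ms post-trigger
    d <- d[d != 0]
    expect_gte(sum(diff(sign(d)) != 0), 3)
  }
})

test_that("every non-header archetype shares the trigger contract", {
  for (a in c("spike", "ringing", "multi")) for (s in 1:15) {
    r <- resultant(simulate_nonheader_trace(toy_params, seed = s,
                                            archetype = a))
    expect_gte(r[11], 8)
    expect_lt(max(r[1:10]), 8)
  }
})

test_that("session simulation is deterministic and category counts add up", {
  cfg <- session_config(n_headers = 30, n_out_of_match = 40, n_off_pitch = 25)
  sim <- simulate_session(cfg, toy_params, seed = 11)
  sim2 <- simulate_session(cfg, toy_params, seed = 11)
  expect_identical(sim, sim2)
  expect_equal(nrow(sim$video), 30L)
  tab <- table(sim$truth$category)
  expect_equal(unname(tab[["spurious_out_of_match"]]), 40L)
  expect_equal(unname(tab[["spurious_off_pitch"]]), 25L)
  n_cap <- unname(tab[["header"]])
  expect_equal(unname(tab[["spurious_in_match"]]), round(21 * n_cap))
  # every emitted trace satisfies the trigger invariant
  for (i in seq_len(length(sim$events))) {
    r <- resultant(matrix(sim$events$traces[i, , ], 3, 100))
    expect_gte(r[11], 8)
    expect_lt(max(r[1:10]), 8)
  }
})

test_that("the sensor miss rate reproduces the configured capture fraction", {
  cfg <- session_config(n_headers = 300, miss_rate = 0.11, nh_per_vh = 2,
                        n_out_of_match = 0, n_off_pitch = 0)
  sim <- simulate_session(cfg, toy_params, seed = 5)
  n_cap <- sum(sim$truth$category == "header")
  expected <- 0.89 * 300
  halfwidth <- 1.96 * sqrt(300 * 0.11 * 0.89)
  expect_lt(abs(n_cap - expected), halfwidth + 1)
})

test_that("the in-match class imbalance tracks the configured ratio", {
  cfg <- session_config(n_headers = 250, nh_per_vh = 21,
                        n_out_of_match = 0, n_off_pitch = 0)
  sim <- simulate_session(cfg, toy_params, seed = 9)
  n_vh <- sum(sim$truth$true_label == "VH")
  n_nh <- sum(sim$truth$true_label == "NH")
  expect_gt(n_vh + n_nh, 4500)
  expect_true(n_nh / n_vh >= 19 && n_nh / n_vh <= 23)
})

test_that("a degenerate configuration yields pure, fully matched headers", {
  cfg <- session_config(n_headers = 25, miss_rate = 0, nh_per_vh = 1e-9,
                        n_out_of_match = 0, n_off_pitch = 0)
  sim <- simulate_session(cfg, toy_params, seed = 13)
  expect_true(all(sim$truth$category == "header"))
  gt <- build_ground_truth(sim$events, sim$video, sim$schedule)
  expect_true(all(gt$labeled$meta$label == "VH"))
  expect_equal(gt$report$unmatched_video_headers, 0L)
})

test_that("infeasible rosters are rejected", {
  expect_error(session_config(n_players = 10, n_on_pitch = 11),
               "more simultaneous players than roster")
  expect_error(session_config(n_substitutions = 5, n_players = 13),
               "bench too small")
})
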