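test_that("z-normalization standardises each axis exactly", {
  tr <- simulate_header_trace(toy_params, seed = 2)
  z <- znormalize(tr)
  expect_true(all(abs(rowMeans(z)) < 1e-9))
  expect_true(all(abs(apply(z, 1, sd) - 1) < 1e-9))
  # idempotence
  expect_equal(znormalize(z), z, tolerance = 1e-9)
  # closed form on a linear ramp 0..99
  ramp <- rbind(0:99, 0:99, 0:99)
  zr <- znormalize(ramp)
  sd_ramp <- sqrt((100^2 - 1) / 12 * 100 / 99)  # sample sd of 0..99
  expect_equal(zr[1, ], ((0:99) - 49.5) / sd_ramp, tolerance = 1e-12)
  # amplitude invariance: scaling by c > 0 leaves the output unchanged
  expect_equal(znormalize(3.7 * tr), z, tolerance = 1e-9)
  # degenerate constant axis is flagged, not coerced
  bad <- tr; bad[2, ] <- 5
  expect_error(znormalize(bad), "degenerate")
})

test_that("pink noise has unit variance and a 1/f spectrum", {
  x <- make_pink_noise(100, seed = 3)
  expect_identical(x, make_pink_noise(100, seed = 3))
  expect_equal(var(x), 1, tolerance = 0.05)
  expect_error(make_pink_noise(4), ">= 8")
  # PSD slope over the central decade, averaged over 500 realizations
  set.seed(42)
  n <- 100
  psum <- numeric(n %/% 2 - 1)
  reps <- 500
  for (i in seq_len(reps)) {
    sp <- abs(fft(make_pink_noise(n)))^2
    psum <- psum + sp[2:(n %/% 2)]
  }
  f <- (1:(n %/% 2 - 1)) * (1000 / n)        # Hz
  keep <- f >= 30 & f <= 300                 # central decade
  fit <- lm(log(psum[keep] / reps) ~ log(f[keep]))
  expect_true(abs(coef(fit)[2] + 1) < 0.25)
})

test_that("scaled pink noise has the prescribed variance", {
  tr <- simulate_header_trace(toy_params, seed = 5)
  sigma <- 0.10
  scale <- sigma * sd(tr[1, ])
  set.seed(1)
  v <- mean(replicate(200, var(scale * make_pink_noise(100))))
  expect_equal(v, scale^2, tolerance = 0.05 * scale^2)
})

test_that("augmentation balances classes with flagged pink-noise copies", {
  ds <- make_labeled_set(10, 210, seed0 = 3)
  out <- augment_balance(ds, augmentation_spec(), seed = 4)
  expect_equal(sum(out$meta$label == "VH"), 210L)
  expect_equal(sum(out$meta$label == "NH"), 210L)
  expect_equal(sum(out$meta$augmented), 200L)
  # originals pass through untouched
  expect_equal(out$traces[seq_len(220), , ], ds$traces)
  expect_equal(out$meta$event_id[seq_len(220)], ds$meta$event_id)
  # an augmented copy differs from its source by roughly sigma in relative RMS
  aug_i <- which(out$meta$augmented)[1]
  src_id <- sub("_aug\\d+$", "", out$meta$event_id[aug_i])
  src_i <- match(src_id, ds$meta$event_id)
  rel <- sqrt(mean(vapply(1:3, function(a) {
    d <- out$traces[aug_i, a, ] - ds$traces[src_i, a, ]
    mean(d^2) / var(ds$traces[src_i, a, ])
  }, numeric(1))))
  expect_gt(rel, 0.05)
  expect_lt(rel, 0.15)
})

test_that("already balanced datasets are returned unchanged", {
  ds <- make_labeled_set(5, 5)
  out <- augment_balance(ds, augmentation_spec(), seed = 1)
  expect_equal(nrow(out$meta), 10L)
  expect_true(all(!out$meta$augmented))
  ds_nh <- make_labeled_set(0, 3)
  expect_error(augment_balance(ds_nh, augmentation_spec()), "no VH")
})

test_that("splitting reproduces the printed partition sizes", {
  # label-level sizes only depend on counts; traces can be blank
  n_vh <- 904; n_nh <- 19145
  meta <- data.frame(
    event_id = sprintf("e%05d", seq_len(n_vh + n_nh)),
    player_id = "p01", session_id = "s1",
    timestamp_s = seq_len(n_vh + n_nh),
    label = rep(c("VH", "NH"), c(n_vh, n_nh)),
    matched_video_id = c(sprintf("h%04d", seq_len(n_vh)),
                         rep(NA, n_nh)),
    match_offset_s = c(rep(0, n_vh), rep(NA, n_nh)),
    stringsAsFactors = FALSE)
  tr <- array(stats::rnorm((n_vh + n_nh) * 3), c(n_vh + n_nh, 3, 100))
  ds <- event_set(meta, tr)
  parts <- split_events(ds, split_spec(), seed = 8)
  expect_equal(sum(parts$test$meta$label == "VH"), 271L)
  expect_equal(sum(parts$test$meta$label == "NH"), 5743L)
  # disjoint and exhaustive at the id level
  ids <- c(parts$train$meta$event_id, parts$val$meta$event_id,
           parts$test$meta$event_id)
  expect_setequal(ids, meta$event_id)
  expect_equal(anyDuplicated(ids), 0L)
})

test_that("augmented events never reach the test partition", {
  ds <- make_labeled_set(8, 40, seed0 = 11)
  bal <- augment_balance(ds, augmentation_spec(), seed = 2)
  parts <- split_events(bal, split_spec(), seed = 3)
  expect_true(all(!parts$test$meta$augmented))
  # everything-in-train split
  all_train <- split_events(ds, split_spec(fractions = c(1, 0, 0)), seed = 1)
  expect_equal(nrow(all_train$train$meta), nrow(ds$meta))
  expect_equal(nrow(all_train$test$meta), 0L)
  # infeasible tiny dataset
  tiny <- make_labeled_set(1, 1)
  expect_error(split_events(tiny, split_spec(), seed = 1), "too small")
})
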