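test_that("confusion tallies are exhaustive and match a hand recount", {
  truth <- rep(c("VH", "NH"), each = 5)
  cc <- confusion_counts(truth, truth)
  expect_equal(unlist(cc[c("TP", "FP", "TN", "FN")]),
               c(TP = 5, FP = 0, TN = 5, FN = 0))
  inv <- ifelse(truth == "VH", "NH", "VH")
  cci <- confusion_counts(inv, truth)
  expect_equal(unlist(cci[c("TP", "FP", "TN", "FN")]),
               c(TP = 0, FP = 5, TN = 0, FN = 5))
  set.seed(12)
  p200 <- sample(c("VH", "NH"), 200, TRUE)
  t200 <- sample(c("VH", "NH"), 200, TRUE)
  cc2 <- confusion_counts(p200, t200)
  hand <- c(TP = 0, FP = 0, TN = 0, FN = 0)
  for (i in 1:200) {
    k <- if (t200[i] == "VH") if (p200[i] == "VH") "TP" else "FN"
         else if (p200[i] == "VH") "FP" else "TN"
    hand[k] <- hand[k] + 1
  }
  expect_equal(unlist(cc2[c("TP", "FP", "TN", "FN")]), hand)
  expect_equal(cc2$TP + cc2$FN, sum(t200 == "VH"))
  expect_equal(cc2$TN + cc2$FP, sum(t200 == "NH"))
  expect_error(confusion_counts(p200[-1], t200), "length")
})

test_that("metrics are the exact defining ratios", {
  cc <- confusion_counts(
    rep(c("VH", "NH"), c(60, 140)),
    rep(c("VH", "NH", "VH", "NH"), c(50, 10, 20, 120)))
  m <- classification_metrics(cc)
  expect_equal(m$sensitivity, cc$TP / (cc$TP + cc$FN), tolerance = 1e-12)
  expect_equal(m$specificity, cc$TN / (cc$TN + cc$FP), tolerance = 1e-12)
  expect_equal(m$precision, cc$TP / (cc$TP + cc$FP), tolerance = 1e-12)
  expect_equal(m$accuracy, (cc$TP + cc$TN) / 200, tolerance = 1e-12)
  expect_equal(m$f1, 2 * m$sensitivity * m$precision /
                 (m$sensitivity + m$precision), tolerance = 1e-12)
})

test_that("zero denominators yield flagged undefined metrics, never 0", {
  m <- classification_metrics(as_confusion_counts(0, 0, 10, 0))
  expect_true(is.na(m$sensitivity))  # no positives in truth
  expect_true(is.na(m$precision))    # no predicted positives
  expect_false(is.na(m$specificity))
  expect_output(print(m), "n/a")
})

test_that("percentages round half-up to one decimal", {
  expect_equal(as_percent(0.9299), 93.0)
  expect_equal(as_percent(0.94465), 94.5)
  expect_equal(as_percent(0.045), 4.5)
  expect_equal(as_percent(0.63049 / 10), 6.3)
  expect_true(is.na(as_percent(NA_real_)))
})

test_that("accuracy is the class-frequency-weighted mix of sens and spec", {
  set.seed(3)
  for (k in 1:20) {
    cc <- as_confusion_counts(TP = sample(0:50, 1), FP = sample(0:50, 1),
                              TN = sample(1:50, 1), FN = sample(1:50, 1))
    m <- classification_metrics(cc)
    npos <- cc$TP + cc$FN; nneg <- cc$TN + cc$FP
    if (!is.na(m$sensitivity) && !is.na(m$specificity)) {
      mix <- (npos * m$sensitivity + nneg * m$specificity) / (npos + nneg)
      expect_equal(m$accuracy, mix, tolerance = 1e-12)
    }
  }
})

test_that("subsampling negatives preserves sensitivity and lowers precision", {
  set.seed(8)
  truth <- rep(c("VH", "NH"), c(100, 2100))
  pred <- truth
  flipv <- sample(which(truth == "VH"), 10)   # 90% sensitivity
  flipn <- sample(which(truth == "NH"), 105)  # 5% false-positive rate
  pred[flipv] <- "NH"; pred[flipn] <- "VH"
  m_full <- classification_metrics(confusion_counts(pred, truth))
  # balanced subsample of negatives
  keep <- c(which(truth == "VH"),
            sample(which(truth == "NH"), 100))
  m_bal <- classification_metrics(confusion_counts(pred[keep], truth[keep]))
  expect_equal(m_bal$sensitivity, m_full$sensitivity, tolerance = 1e-12)
  expect_gt(m_bal$precision, m_full$precision)
})

test_that("an injected oracle classifier scores 100% everywhere", {
  ds <- make_labeled_set(12, 40, seed0 = 200)
  oracle <- function(test) test$meta$label
  res <- run_scenario(ds, scenario = "balanced", folds = 2,
                      methods = list(oracle = oracle),
                      split = split_spec(c(0.5, 0.2, 0.3)), seed = 4)
  m <- res$scenarios$balanced$mean_metrics$oracle
  expect_equal(unlist(m), c(sensitivity = 1, specificity = 1, precision = 1,
                            accuracy = 1, f1 = 1))
})

test_that("threshold baselines are deterministic across repeated folds", {
  ds <- make_labeled_set(12, 60, seed0 = 300)
  res <- run_scenario(ds, scenario = "unbalanced", folds = 3,
                      methods = c("thr10", "thr16"), seed = 5)
  fm <- res$scenarios$unbalanced$fold_metrics
  # identical metrics whenever two folds share a test partition is implied
  # by determinism on a fixed partition; check the rule directly instead
  one <- ds[ds$meta$label == "NH"]
  expect_identical(threshold_classify(one, 10), threshold_classify(one, 10))
  # 16 g is strictly more conservative than 10 g on every fold
  s10 <- fm$sensitivity[fm$method == "thr10"]
  s16 <- fm$sensitivity[fm$method == "thr16"]
  expect_true(all(s16 <= s10))
  p10 <- fm$specificity[fm$method == "thr10"]
  p16 <- fm$specificity[fm$method == "thr16"]
  expect_true(all(p16 >= p10))
})

test_that("fold averaging reports the mean of per-fold metrics", {
  ds <- make_labeled_set(12, 40, seed0 = 400)
  res <- run_scenario(ds, scenario = "balanced", folds = 3,
                      methods = c("thr10"), seed = 6)
  fm <- res$scenarios$balanced$fold_metrics
  mm <- res$scenarios$balanced$mean_metrics$thr10
  expect_equal(mm$sensitivity, mean(fm$sensitivity), tolerance = 1e-12)
  # pooled metrics come from summed counts (both conventions reported)
  pooled <- res$scenarios$balanced$pooled_counts$thr10
  expect_equal(pooled$TP, sum(fm$TP))
  expect_equal(res$scenarios$balanced$pooled_metrics$thr10$sensitivity,
               pooled$TP / (pooled$TP + pooled$FN), tolerance = 1e-12)
})

test_that("scenario reports round-trip through the written tables", {
  ds <- make_labeled_set(12, 40, seed0 = 500)
  res <- run_scenario(ds, scenario = "balanced", folds = 2,
                      methods = c("thr10", "thr16"), seed = 7)
  dir <- withr::local_tempdir()
  write_scenario_report(res, dir)
  tab <- read_metrics_table(file.path(dir, "metrics_balanced.csv"))
  in_mem <- headrec:::scenario_table(res, "balanced")
  for (mn in c("thr10", "thr16")) {
    num <- suppressWarnings(as.numeric(tab[[mn]]))
    expect_equal(num[!is.na(num)], in_mem[[mn]][!is.na(in_mem[[mn]])])
    # undefined metrics are rendered as n/a, never 0
    expect_equal(is.na(num), is.na(in_mem[[mn]]))
    expect_false(any(tab[[mn]] == "0", na.rm = TRUE))
  }
  expect_true(file.exists(file.path(dir, "report.md")))
  expect_true(file.exists(file.path(dir, "confusion_thr10_balanced.csv")))
})
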