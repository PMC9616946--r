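#' Confusion counts for header classification
#'
#' Tallies the 2x2 confusion matrix with the valid header (`VH`) as the
#' positive class: `TP` a header classified as header, `FP` a non-header
#' classified as header, `TN` a non-header classified as non-header, `FN`
#' a header classified as non-header. Counts may be non-integer when
#' averaged over folds.
#'
#' @param predicted,truth equal-length vectors of `"VH"`/`"NH"` labels.
#' @return An object of class `confusion_counts` with fields `TP`, `FP`,
#'   `TN`, `FN`.
#' @export
confusion_counts <- function(predicted, truth) {
  if (length(predicted) != length(truth))
    stop("predicted and truth differ in length")
  if (!all(c(predicted, truth) %in% c("VH", "NH")))
    stop("labels must be 'VH' or 'NH'")
  structure(list(TP = sum(predicted == "VH" & truth == "VH"),
                 FP = sum(predicted == "VH" & truth == "NH"),
                 TN = sum(predicted == "NH" & truth == "NH"),
                 FN = sum(predicted == "NH" & truth == "VH")),
            class = "confusion_counts")
}

#' @rdname confusion_counts
#' @param TP,FP,TN,FN non-negative counts (possibly fold-averaged reals).
#' @export
as_confusion_counts <- function(TP, FP, TN, FN) {
  if (any(c(TP, FP, TN, FN) < 0)) stop("counts must be >= 0")
  structure(list(TP = TP, FP = FP, TN = TN, FN = FN),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  m <- matrix(c(x$TP, x$FN, x$FP, x$TN), 2, 2,
              dimnames = list(predicted = c("VH", "NH"),
                              truth = c("VH", "NH")))
  print(m)
  invisible(x)
}

#' Classification performance metrics
#'
#' Computes the five performance metrics from confusion counts:
#' \deqn{Sensitivity = TP/(TP+FN)}
#' \deqn{Specificity = TN/(TN+FP)}
#' \deqn{Precision = TP/(TP+FP)}
#' \deqn{Accuracy = (TP+TN)/(TP+FP+TN+FN)}
#' \deqn{F1 = 2\,(Sensitivity \cdot Precision)/(Sensitivity + Precision)}
#' A metric with a zero denominator is undefined and returned as `NA`
#' (flagged, never coerced to 0). Values are proportions in `[0, 1]`; the
#' print method reports percentages rounded half-up to one decimal.
#'
#' @param counts a [confusion_counts()].
#' @return An object of class `metrics_report`: a named list with
#'   `sensitivity`, `specificity`, `precision`, `accuracy`, `f1`.
#' @examples
#' m <- classification_metrics(as_confusion_counts(248, 15, 256, 23))
#' m  # sensitivity 91.5%, precision 94.3%, ...
#' @export
classification_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  rat <- function(num, den) if (den > 0) num / den else NA_real_
  sens <- rat(counts$TP, counts$TP + counts$FN)
  spec <- rat(counts$TN, counts$TN + counts$FP)
  prec <- rat(counts$TP, counts$TP + counts$FP)
  acc <- rat(counts$TP + counts$TN,
             counts$TP + counts$FP + counts$TN + counts$FN)
  f1 <- if (!is.na(sens) && !is.na(prec) && (sens + prec) > 0)
    2 * sens * prec / (sens + prec) else NA_real_
  structure(list(sensitivity = sens, specificity = spec, precision = prec,
                 accuracy = acc, f1 = f1),
            class = "metrics_report")
}

#' Round half-up to one decimal, as a percentage
#'
#' @param p proportion in `[0, 1]` (or `NA`).
#' @param digits decimals of the percentage (default 1).
#' @return Percentage rounded half-up (e.g. `0.92995` -> `93.0`).
#' @export
as_percent <- function(p, digits = 1) {
  ifelse(is.na(p), NA_real_,
         floor(p * 100 * 10^digits + 0.5) / 10^digits)
}

#' @export
print.metrics_report <- function(x, ...) {
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-12s %s\n", nm,
                if (is.na(v)) "n/a" else sprintf("%.1f%%", as_percent(v))))
  }
  invisible(x)
}

#' Run a balanced or unbalanced test scenario
#'
#' Evaluates classification methods under repeated random splitting: for
#' each of `folds` folds the labelled dataset is freshly partitioned
#' (stratified 49/21/30 by default), the training and validation
#' partitions are class-balanced by pink-noise augmentation, the network
#' is trained, and every method is evaluated on the identical test
#' partition. In the balanced scenario the test non-headers are randomly
#' subsampled to the valid-header count; the unbalanced scenario uses the
#' full test partition (the native ~1/21 class ratio). Metrics are
#' averaged across folds (the mean of per-fold metrics); metrics of the
#' summed counts are reported alongside.
#'
#' @param labeled a labelled [event_set()] (both classes present).
#' @param scenario `"balanced"`, `"unbalanced"`, or both (evaluated on the
#'   same trained folds).
#' @param folds number of repeated splits (default 5, minimum 2).
#' @param methods named list/vector of methods: the strings `"lstm"`,
#'   `"thr10"`, `"thr16"`, or a function `f(test_events)` returning
#'   `"VH"`/`"NH"` labels.
#' @param net a [network_config()] for the `lstm` method.
#' @param cfg a [training_config()] for the `lstm` method.
#' @param split a [split_spec()].
#' @param augment an [augmentation_spec()].
#' @param seed integer seed; fold `i` uses seed `seed + i`.
#' @param verbose print per-fold progress.
#' @return An object of class `scenario_result`: for each scenario a list
#'   with `fold_metrics` (data frame of per-fold metric rows),
#'   `mean_metrics` (per-method fold-averaged [classification_metrics()]),
#'   `pooled_counts` and `pooled_metrics` (per-method sums over folds and
#'   their metrics), plus `folds`, `methods`, `scenario`.
#' @export
run_scenario <- function(labeled, scenario = "balanced", folds = 5,
                         methods = c("lstm", "thr10", "thr16"),
                         net = network_config(), cfg = training_config(),
                         split = split_spec(), augment = augmentation_spec(),
                         seed = 1, verbose = FALSE) {
  stopifnot(inherits(labeled, "event_set"))
  if (folds < 2) stop("folds must be >= 2")
  scenario <- match.arg(scenario, c("balanced", "unbalanced"),
                        several.ok = TRUE)
  if (!"label" %in% names(labeled$meta)) stop("dataset must be labelled")
  if (length(unique(labeled$meta$label)) < 2)
    stop("dataset must contain both classes")
  if (is.null(names(methods)))
    names(methods) <- vapply(seq_along(methods), function(i)
      if (is.character(methods[[i]])) methods[[i]] else paste0("custom", i),
      character(1))

  needs_lstm <- any(vapply(methods, function(m)
    is.character(m) && m == "lstm", logical(1)))
  rows <- list()
  for (fold in seq_len(folds)) {
    fold_seed <- seed + fold
    parts <- split_events(labeled, split, seed = fold_seed)
    train_bal <- augment_balance(parts$train, augment, seed = fold_seed + 1000L)
    val_bal <- augment_balance(parts$val, augment, seed = fold_seed + 2000L)
    fit <- NULL
    if (needs_lstm) {
      cfg_fold <- cfg; cfg_fold$seed <- cfg$seed + fold
      fit <- fit_bilstm(train_bal, net = net, cfg = cfg_fold,
                        validation = val_bal)
    }
    test_sets <- list()
    for (sc in scenario) {
      if (sc == "balanced") {
        vh_idx <- which(parts$test$meta$label == "VH")
        nh_idx <- which(parts$test$meta$label == "NH")
        nh_take <- with_seed(fold_seed + 3000L,
                             nh_idx[sample.int(length(nh_idx),
                                               min(length(vh_idx),
                                                   length(nh_idx)))])
        test_sets[[sc]] <- parts$test[sort(c(vh_idx, nh_take))]
      } else test_sets[[sc]] <- parts$test
    }
    for (sc in scenario) {
      test <- test_sets[[sc]]
      truth <- test$meta$label
      for (mn in names(methods)) {
        m <- methods[[mn]]
        pred <- if (is.function(m)) m(test)
        else switch(m,
                    lstm = predict(fit, test),
                    thr10 = threshold_classify(test, 10),
                    thr16 = threshold_classify(test, 16),
                    stop("unknown method: ", m))
        cc <- confusion_counts(pred, truth)
        met <- classification_metrics(cc)
        rows[[length(rows) + 1]] <- data.frame(
          scenario = sc, fold = fold, method = mn,
          TP = cc$TP, FP = cc$FP, TN = cc$TN, FN = cc$FN,
          sensitivity = met$sensitivity, specificity = met$specificity,
          precision = met$precision, accuracy = met$accuracy, f1 = met$f1)
      }
    }
    if (verbose) message("fold ", fold, " done")
  }
  fold_metrics <- do.call(rbind, rows)
  out <- list()
  for (sc in scenario) {
    fm <- fold_metrics[fold_metrics$scenario == sc, ]
    mean_metrics <- list(); pooled_counts <- list(); pooled_metrics <- list()
    for (mn in names(methods)) {
      mm <- fm[fm$method == mn, ]
      mean_metrics[[mn]] <- structure(
        as.list(colMeans(mm[, c("sensitivity", "specificity", "precision",
                                "accuracy", "f1")])),
        class = "metrics_report")
      pooled_counts[[mn]] <- as_confusion_counts(sum(mm$TP), sum(mm$FP),
                                                 sum(mm$TN), sum(mm$FN))
      pooled_metrics[[mn]] <- classification_metrics(pooled_counts[[mn]])
    }
    out[[sc]] <- list(fold_metrics = fm, mean_metrics = mean_metrics,
                      pooled_counts = pooled_counts,
                      pooled_metrics = pooled_metrics)
  }
  structure(list(scenarios = out, folds = folds, methods = names(methods),
                 scenario = scenario),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  for (sc in x$scenario) {
    cat("Scenario: ", sc, " (", x$folds, "-fold averaged)\n", sep = "")
    print(scenario_table(x, sc), row.names = FALSE)
    cat("\n")
  }
  invisible(x)
}

# one row per metric, one column per method (fold-averaged percentages)
scenario_table <- function(result, scenario) {
  res <- result$scenarios[[scenario]]
  metrics <- c("sensitivity", "specificity", "precision", "accuracy", "f1")
  tab <- data.frame(metric = metrics, stringsAsFactors = FALSE)
  for (mn in names(res$mean_metrics)) {
    v <- unlist(res$mean_metrics[[mn]])[metrics]
    tab[[mn]] <- ifelse(is.na(v), NA, as_percent(v))
  }
  tab
}

#' Write a scenario comparison report
#'
#' Writes the fold-averaged metric table (`metrics.csv`, one row per
#' metric and one column per method, percentages to one decimal; undefined
#' metrics rendered as `n/a`), per-method pooled confusion matrices
#' (`confusion_<method>.csv`) and a human-readable `report.md` into a
#' directory.
#'
#' @param result a `scenario_result` from [run_scenario()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_scenario_report <- function(result, dir) {
  stopifnot(inherits(result, "scenario_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  md <- c("# Classification report", "")
  for (sc in result$scenario) {
    tab <- scenario_table(result, sc)
    out <- tab
    for (cl in names(out)[-1])
      out[[cl]] <- ifelse(is.na(out[[cl]]), "n/a",
                          sprintf("%.1f", out[[cl]]))
    utils::write.csv(out, file.path(dir, paste0("metrics_", sc, ".csv")),
                     row.names = FALSE, quote = FALSE)
    res <- result$scenarios[[sc]]
    for (mn in names(res$pooled_counts)) {
      cc <- res$pooled_counts[[mn]]
      utils::write.csv(data.frame(truth = c("VH", "NH"),
                                  predicted_VH = c(cc$TP, cc$FP),
                                  predicted_NH = c(cc$FN, cc$TN)),
                       file.path(dir, sprintf("confusion_%s_%s.csv", mn, sc)),
                       row.names = FALSE, quote = FALSE)
    }
    md <- c(md, paste0("## ", sc, " scenario (", result$folds,
                       "-fold averaged, %)"), "",
            paste(names(out), collapse = " | "),
            paste(rep("---", ncol(out)), collapse = " | "),
            apply(out, 1, paste, collapse = " | "), "")
  }
  writeLines(md, file.path(dir, "report.md"))
  invisible(dir)
}
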