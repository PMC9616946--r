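#' Z-normalize acceleration traces
#'
#' Standardises each axis of each event to mean 0 and standard deviation 1
#' (denominator `n - 1`). Normalisation is per event and per axis, so
#' classification depends on the structural shape of a profile rather than
#' its amplitude: scaling a raw trace by any positive constant yields an
#' identical normalized trace.
#'
#' @param x a `3 x 100` trace matrix or an [event_set()].
#' @param ... unused.
#' @return An object of the same shape with each axis standardised. An axis
#'   with zero variance is a degenerate input and raises an error
#'   (for an `event_set` the error names the offending event, which the
#'   caller may exclude).
#' @examples
#' tr <- simulate_header_trace(waveform_params(), seed = 1)
#' z <- znormalize(tr)
#' rowMeans(z); apply(z, 1, sd)
#' @export
znormalize <- function(x, ...) UseMethod("znormalize")

#' @rdname znormalize
#' @export
znormalize.default <- function(x, ...) {
  stopifnot(is.matrix(x))
  m <- rowMeans(x)
  s <- apply(x, 1, stats::sd)
  if (any(s == 0)) stop("degenerate input: constant axis cannot be z-normalized")
  (x - m) / s
}

#' @rdname znormalize
#' @export
znormalize.event_set <- function(x, ...) {
  n <- nrow(x$meta)
  for (i in seq_len(n)) {
    tr <- matrix(x$traces[i, , ], N_AXES, N_SAMPLES)
    s <- apply(tr, 1, stats::sd)
    if (any(s == 0))
      stop("degenerate input: constant axis in event ", x$meta$event_id[i])
    x$traces[i, , ] <- (tr - rowMeans(tr)) / s
  }
  x
}

#' Generate pink (1/f) noise
#'
#' Produces a unit-variance pink-noise sequence by spectral shaping: a white
#' Gaussian sequence is transformed to the frequency domain, its amplitude
#' spectrum multiplied by \eqn{f^{-1/2}} (so the power spectral density
#' falls as \eqn{1/f}), the DC bin zeroed, and the result transformed back
#' and scaled to unit sample variance.
#'
#' @param n sequence length, at least 8.
#' @param seed optional integer seed.
#' @return Numeric vector of length `n` with sample mean 0 and sample
#'   variance 1.
#' @export
make_pink_noise <- function(n = 100, seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 8)
    stop("n must be a single integer >= 8")
  n <- as.integer(n)
  with_seed(seed, {
    w <- stats::rnorm(n)
    spec <- stats::fft(w)
    k <- 0:(n - 1)
    f <- pmin(k, n - k)          # symmetric frequency index; keeps Hermitian
    shape <- c(0, 1 / sqrt(f[-1]))
    x <- Re(stats::fft(spec * shape, inverse = TRUE)) / n
    x <- x - mean(x)
    x / stats::sd(x)
  })
}

#' Balance classes by pink-noise augmentation
#'
#' Increases the minority valid-header class to the non-header count by
#' copying uniformly sampled VH events and adding independent per-axis pink
#' noise scaled by `sigma` times the per-axis standard deviation of the
#' copied raw trace. Noise is added to the raw (pre-normalisation) trace;
#' originals are returned unchanged and augmented copies carry
#' `augmented = TRUE` and a fresh event id.
#'
#' @param dataset a labelled [event_set()] containing at least one VH.
#' @param spec an [augmentation_spec()].
#' @param seed optional integer seed.
#' @return An [event_set()] with equal VH and NH counts (for the default
#'   target ratio of 1) and an `augmented` flag column.
#' @export
augment_balance <- function(dataset, spec = augmentation_spec(), seed = NULL) {
  stopifnot(inherits(dataset, "event_set"), inherits(spec, "augmentation_spec"))
  meta <- dataset$meta
  if (!"label" %in% names(meta)) stop("dataset must be labelled")
  if (!"augmented" %in% names(meta)) meta <- cbind(meta, augmented = FALSE)
  dataset$meta <- meta
  n_vh <- sum(meta$label == "VH"); n_nh <- sum(meta$label == "NH")
  if (n_vh == 0) stop("cannot balance: dataset contains no VH")
  target <- round(spec$ratio * n_nh)
  n_add <- target - n_vh
  if (n_add <= 0) return(dataset)
  with_seed(seed, {
    vh_idx <- which(meta$label == "VH")
    src <- vh_idx[sample.int(n_vh, n_add, replace = TRUE)]
    add_meta <- meta[src, , drop = FALSE]
    add_meta$event_id <- sprintf("%s_aug%04d", add_meta$event_id, seq_len(n_add))
    add_meta$augmented <- TRUE
    rownames(add_meta) <- NULL
    add_traces <- array(0, c(n_add, N_AXES, N_SAMPLES))
    for (j in seq_len(n_add)) {
      tr <- matrix(dataset$traces[src[j], , ], N_AXES, N_SAMPLES)
      for (a in seq_len(N_AXES)) {
        scale <- spec$sigma * stats::sd(tr[a, ])
        tr[a, ] <- tr[a, ] + scale * make_pink_noise(N_SAMPLES)
      }
      add_traces[j, , ] <- tr
    }
    combine_event_sets(dataset, event_set(add_meta, add_traces))
  })
}

#' Partition a labelled dataset for training, validation and testing
#'
#' Randomly allocates events to train/validation/test partitions with the
#' configured fractions (default 49/21/30). With stratification the
#' fractions are applied within each class label; the test share is rounded
#' down (so 30% of 904 VHs gives 271 and 30% of 19,145 NHs gives 5743), the
#' validation share is rounded to nearest, and the remainder goes to
#' training. Augmented events, if present, are never placed in the test
#' partition.
#'
#' @param dataset a labelled [event_set()].
#' @param spec a [split_spec()].
#' @param seed optional integer seed.
#' @return A list of [event_set()] partitions `train`, `val`, `test`;
#'   disjoint, with union equal to the input.
#' @export
split_events <- function(dataset, spec = split_spec(), seed = NULL) {
  stopifnot(inherits(dataset, "event_set"), inherits(spec, "split_spec"))
  meta <- dataset$meta
  n <- nrow(meta)
  if (!n) stop("dataset is empty")
  fr <- spec$fractions
  groups <- if (spec$stratify && "label" %in% names(meta))
    split(seq_len(n), meta$label) else list(all = seq_len(n))
  part <- character(n)
  with_seed(seed, {
    for (idx in groups) {
      m <- length(idx)
      aug_all <- if ("augmented" %in% names(meta))
        isTRUE_vec(meta$augmented[idx]) else rep(FALSE, m)
      # the test share is a share of the real (non-augmented) events
      n_test <- floor(fr[["test"]] * sum(!aug_all))
      n_val <- round(fr[["val"]] * m)
      n_train <- m - n_test - n_val
      if ((fr[["test"]] > 0 && n_test == 0) ||
          (fr[["val"]] > 0 && n_val == 0) ||
          (fr[["train"]] > 0 && n_train <= 0))
        stop("dataset too small for the requested split fractions")
      # test drawn from non-augmented events only
      pool_test <- idx[!aug_all]
      if (length(pool_test) < n_test)
        stop("not enough non-augmented events for the test partition")
      test_idx <- pool_test[sample.int(length(pool_test), n_test)]
      rest <- setdiff(idx, test_idx)
      val_idx <- rest[sample.int(length(rest), n_val)]
      part[test_idx] <- "test"
      part[val_idx] <- "val"
      part[setdiff(rest, val_idx)] <- "train"
    }
  })
  list(train = dataset[part == "train"],
       val = dataset[part == "val"],
       test = dataset[part == "test"])
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)
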