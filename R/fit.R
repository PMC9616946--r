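#' Fit the bidirectional LSTM header classifier
#'
#' Trains the sequence classifier on labelled triggered-event traces with
#' mini-batch gradient descent under the moving-average adaptive moment
#' update ([adam_step()]). Traces are z-normalised per event and axis
#' before entering the network (so classification is amplitude-invariant);
#' the loss is the cross entropy of the two-class softmax plus an L2
#' penalty on the weight matrices. Training runs `cfg$epochs` passes over
#' freshly shuffled mini-batches and is deterministic given the seed in
#' `cfg`.
#'
#' @param x training data: a labelled [event_set()], or an `[n, 3, 100]`
#'   array of raw traces (then `y` is required).
#' @param y class labels (`"VH"`/`"NH"`, character or factor); taken from
#'   `x$meta$label` when `x` is a labelled event set.
#' @param net a [network_config()].
#' @param cfg a [training_config()].
#' @param validation optional validation data (same forms as `x`/`y`):
#'   a labelled event set or `list(x = , y = )`; per-epoch validation loss
#'   and sensitivity are recorded in the history.
#' @param verbose print per-epoch progress.
#' @return An object of class `bilstm_fit` with components `params`
#'   (trained parameters), `net`, `cfg`, `history` (data frame of per-epoch
#'   training/validation loss and sensitivity) and `n_train`.
#' @seealso [predict.bilstm_fit()], [tune_bilstm()], [threshold_classify()]
#' @examples
#' \donttest{
#' params <- waveform_params()
#' n <- 60
#' tr <- array(0, c(n, 3, 100))
#' for (i in 1:30) tr[i, , ] <- simulate_header_trace(params, seed = i)
#' for (i in 31:60) tr[i, , ] <- simulate_nonheader_trace(params, seed = i)
#' y <- rep(c("VH", "NH"), each = 30)
#' fit <- fit_bilstm(tr, y, net = network_config(hidden = 8),
#'                   cfg = training_config(alpha = 0.05, batch_size = 20,
#'                                         epochs = 2, seed = 1))
#' fit
#' }
#' @export
fit_bilstm <- function(x, y = NULL, net = network_config(),
                       cfg = training_config(), validation = NULL,
                       verbose = FALSE) {
  stopifnot(inherits(net, "network_config"), inherits(cfg, "training_config"))
  d <- as_training_data(x, y)
  if (!nrow(d$x)) stop("empty training set")
  val <- if (!is.null(validation)) as_training_data(validation) else NULL

  params <- bilstm_init(net, seed = cfg$seed)
  state <- adam_init(params)
  n <- dim(d$x)[1]
  hist <- NULL
  with_seed(cfg$seed + 1L, {
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      starts <- seq(1, n, by = cfg$batch_size)
      ep_loss <- 0; ep_n <- 0
      tp <- 0; fn <- 0
      for (s in starts) {
        idx <- ord[s:min(s + cfg$batch_size - 1, n)]
        out <- bilstm_loss_grads(params,
                                 d$x[idx, , , drop = FALSE], d$y[idx],
                                 lambda = cfg$lambda)
        up <- adam_step(params, out$grads, state, cfg)
        params <- up$params; state <- up$state
        ep_loss <- ep_loss + out$ce * length(idx); ep_n <- ep_n + length(idx)
        pred_vh <- out$probs[, 1] >= 0.5
        tp <- tp + sum(pred_vh & d$y[idx] == 1L)
        fn <- fn + sum(!pred_vh & d$y[idx] == 1L)
      }
      row <- data.frame(epoch = epoch, train_loss = ep_loss / ep_n,
                        train_sensitivity = if (tp + fn) tp / (tp + fn) else NA,
                        val_loss = NA_real_, val_sensitivity = NA_real_)
      if (!is.null(val)) {
        vp <- forward_chunked(params, val$x)
        eps <- 1e-12
        row$val_loss <- -mean(log(pmax(
          vp[cbind(seq_len(nrow(vp)), val$y)], eps)))
        vvh <- val$y == 1L
        row$val_sensitivity <- if (any(vvh))
          sum(vp[vvh, 1] >= 0.5) / sum(vvh) else NA
      }
      hist <- rbind(hist, row)
      if (verbose)
        message(sprintf("epoch %d  loss %.4f  val loss %s", epoch,
                        row$train_loss,
                        ifelse(is.na(row$val_loss), "-",
                               sprintf("%.4f", row$val_loss))))
    }
  })
  structure(list(params = params, net = net, cfg = cfg, history = hist,
                 n_train = n),
            class = "bilstm_fit")
}

# normalise the accepted training-data forms to list(x = array, y = int 1/2)
as_training_data <- function(x, y = NULL) {
  if (inherits(x, "event_set")) {
    if (is.null(y)) {
      if (!"label" %in% names(x$meta)) stop("event set carries no labels")
      y <- x$meta$label
    }
    # canonical order: training must not depend on event file order
    ord <- order(x$meta$event_id)
    y <- y[ord]
    x <- x$traces[ord, , , drop = FALSE]
  } else if (is.list(x) && !is.array(x) && all(c("x", "y") %in% names(x))) {
    y <- x$y; x <- x$x
  }
  if (is.null(y)) stop("labels y are required")
  x <- as_batch_array(x)
  x <- znorm_array(x)
  if (is.numeric(y) && all(y %in% 1:2)) return(list(x = x, y = as.integer(y)))
  y <- as.character(y)
  if (!all(y %in% c("VH", "NH"))) stop("labels must be 'VH' or 'NH'")
  list(x = x, y = ifelse(y == "VH", 1L, 2L))
}

znorm_array <- function(x) {
  for (i in seq_len(dim(x)[1])) {
    tr <- matrix(x[i, , ], dim(x)[2], dim(x)[3])
    s <- apply(tr, 1, stats::sd)
    if (any(s == 0))
      stop("degenerate input: constant axis in trace ", i)
    x[i, , ] <- (tr - rowMeans(tr)) / s
  }
  x
}

forward_chunked <- function(params, x, chunk = 256L) {
  n <- dim(x)[1]
  out <- matrix(0, n, ncol(params$W2))
  for (s in seq(1, n, by = chunk)) {
    idx <- s:min(s + chunk - 1, n)
    out[idx, ] <- bilstm_forward(params, x[idx, , , drop = FALSE])
  }
  colnames(out) <- c("VH", "NH")
  out
}

#' Predict from a fitted header classifier
#'
#' @param object a `bilstm_fit`.
#' @param newdata an [event_set()], `[n, 3, 100]` array or single `3 x 100`
#'   trace of raw accelerations; traces are z-normalised internally.
#' @param type `"class"` for `"VH"`/`"NH"` labels, `"prob"` for the
#'   softmax probability matrix.
#' @param ... unused.
#' @return Character vector of labels, or an `n x 2` probability matrix.
#' @export
predict.bilstm_fit <- function(object, newdata, type = c("class", "prob"),
                               ...) {
  type <- match.arg(type)
  x <- if (inherits(newdata, "event_set")) newdata$traces
       else as_batch_array(newdata)
  x <- znorm_array(as_batch_array(x))
  p <- forward_chunked(object$params, x)
  if (type == "prob") return(p)
  ifelse(p[, "VH"] >= 0.5, "VH", "NH")
}

#' @export
print.bilstm_fit <- function(x, ...) {
  cat("Bidirectional LSTM header classifier\n",
      "  architecture: ", x$net$n_axes, " axes x ", x$net$n_steps,
      " samples -> BiLSTM(", x$net$hidden, "/direction) -> FC(",
      x$net$fc_nodes, ") -> softmax(", x$net$n_classes, ")\n",
      "  parameters:   ", format(count_parameters(x$params), big.mark = ","),
      "\n  trained on:   ", x$n_train, " events, ", x$cfg$epochs,
      " epoch(s), batch size ", x$cfg$batch_size, "\n", sep = "")
  last <- x$history[nrow(x$history), ]
  cat(sprintf("  final train loss %.4f%s\n", last$train_loss,
              if (!is.na(last$val_loss))
                sprintf(", val loss %.4f", last$val_loss) else ""))
  invisible(x)
}

#' @export
summary.bilstm_fit <- function(object, ...) {
  print(object)
  cat("\nTraining history:\n")
  print(object$history, row.names = FALSE)
  invisible(object$history)
}

#' @export
coef.bilstm_fit <- function(object, ...) object$params

#' @export
plot.bilstm_fit <- function(x, ...) {
  h <- x$history
  ylim <- range(c(h$train_loss, h$val_loss), na.rm = TRUE)
  graphics::plot(h$epoch, h$train_loss, type = "b", ylim = ylim,
                 xlab = "epoch", ylab = "cross-entropy loss", ...)
  if (any(!is.na(h$val_loss))) {
    graphics::lines(h$epoch, h$val_loss, type = "b", lty = 2)
    graphics::legend("topright", legend = c("training", "validation"),
                     lty = 1:2, bty = "n")
  }
  invisible(h)
}

#' @export
residuals.bilstm_fit <- function(object, newdata, ...) {
  d <- as_training_data(newdata)
  p <- forward_chunked(object$params, d$x)
  pt <- pmax(p[cbind(seq_len(nrow(p)), d$y)], 1e-12)
  sign_ <- ifelse(d$y == 1L, 1, -1)   # positive residual for VH
  sign_ * sqrt(-2 * log(pt))          # deviance residuals
}

# total squared norm of the weight matrices (regularization target)
weight_norm <- function(params)
  sqrt(sum(params$fwd$Wx^2) + sum(params$fwd$Wh^2) +
       sum(params$bwd$Wx^2) + sum(params$bwd$Wh^2) +
       sum(params$W1^2) + sum(params$W2^2))

#' Serialise a fitted model to a portable text file
#'
#' Writes shapes, configuration and flat parameter arrays as YAML so a
#' model can be reloaded by any backend.
#'
#' @param object a `bilstm_fit`.
#' @param path output file.
#' @return `read_bilstm()` returns the restored `bilstm_fit` (without
#'   training history).
#' @export
write_bilstm <- function(object, path) {
  stopifnot(inherits(object, "bilstm_fit"))
  flat <- list()
  put <- function(prefix, p) {
    for (nm in names(p)) {
      v <- p[[nm]]
      key <- paste0(prefix, nm)
      if (is.list(v)) put(paste0(key, "."), v)
      else flat[[key]] <<- list(dim = if (is.matrix(v)) dim(v) else length(v),
                                data = as.numeric(v))
    }
  }
  put("", object$params)
  yaml::write_yaml(list(network = unclass(object$net),
                        training = unclass(object$cfg),
                        parameters = flat), path, precision = 12)
  invisible(path)
}

#' @rdname write_bilstm
#' @export
read_bilstm <- function(path) {
  raw <- yaml::read_yaml(path)
  net <- do.call(network_config, raw$network[c("n_axes", "n_steps", "hidden",
                                               "fc_nodes", "n_classes")])
  cfg <- do.call(training_config,
                 raw$training[c("alpha", "batch_size", "lambda", "beta1",
                                "beta2", "epsilon", "epochs",
                                "bias_correction", "seed")])
  params <- list(fwd = list(), bwd = list())
  for (key in names(raw$parameters)) {
    v <- raw$parameters[[key]]
    arr <- if (length(v$dim) == 2) matrix(v$data, v$dim[1], v$dim[2])
           else as.numeric(v$data)
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    if (length(parts) == 2) params[[parts[1]]][[parts[2]]] <- arr
    else params[[parts[1]]] <- arr
  }
  structure(list(params = params, net = net, cfg = cfg,
                 history = NULL, n_train = NA_integer_),
            class = "bilstm_fit")
}
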