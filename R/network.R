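#' Network architecture configuration
#'
#' Fixes the architecture of the sequence classifier: a sequence input of
#' `n_axes` channels and `n_steps` samples feeds a bidirectional LSTM layer
#' with `hidden` units per direction; the concatenated final hidden states
#' of the two directions (length `2 * hidden`) feed a fully connected
#' hidden layer of `fc_nodes` units (tanh), followed by a linear map to
#' `n_classes` outputs and a softmax. The defaults mirror the tuned
#' configuration: 3 axes, 100 samples, 100 hidden units per direction and
#' 43 fully connected nodes for 2 classes.
#'
#' @param n_axes input channels (3 acceleration axes).
#' @param n_steps sequence length (100 samples).
#' @param hidden LSTM hidden units per direction.
#' @param fc_nodes fully connected hidden nodes; tunable in `[20, 100]`.
#' @param n_classes output classes (2: VH, NH).
#' @return A validated list of class `network_config`.
#' @export
network_config <- function(n_axes = 3, n_steps = 100, hidden = 100,
                           fc_nodes = 43, n_classes = 2) {
  cfg <- list(n_axes = as.integer(n_axes), n_steps = as.integer(n_steps),
              hidden = as.integer(hidden), fc_nodes = as.integer(fc_nodes),
              n_classes = as.integer(n_classes))
  if (any(unlist(cfg) <= 0)) stop("network dimensions must be positive")
  if (cfg$fc_nodes < 20 || cfg$fc_nodes > 100)
    stop("fc_nodes must lie in its search range [20, 100]")
  structure(cfg, class = "network_config")
}

#' Training configuration
#'
#' Houses the optimizer and training-loop parameters: the moving-average
#' adaptive moment update uses decay rates `beta1 = 0.9` and
#' `beta2 = 0.99`, smoothing term `epsilon = 1e-8`, and — by default — the
#' update exactly as printed, without bias correction of the moment
#' estimates (`bias_correction = TRUE` switches to the standard
#' bias-corrected variant). Defaults for the tunable parameters are the
#' tuned values: initial learning rate 0.168, mini-batch size 119, L2
#' regularization factor 0.0016; training runs for 3 epochs.
#'
#' @param alpha positive initial learning rate.
#' @param batch_size mini-batch size.
#' @param lambda non-negative L2 regularization factor (applied to weight
#'   matrices only, not biases).
#' @param beta1,beta2 moving-average decay rates in `[0, 1)`.
#' @param epsilon positive smoothing term.
#' @param epochs number of passes over the training set (default 3).
#' @param bias_correction use bias-corrected moment estimates (default
#'   `FALSE`, matching the printed update).
#' @param seed integer seed controlling initialisation and shuffling.
#' @return A validated list of class `training_config`.
#' @export
training_config <- function(alpha = 0.168, batch_size = 119, lambda = 0.0016,
                            beta1 = 0.9, beta2 = 0.99, epsilon = 1e-8,
                            epochs = 3, bias_correction = FALSE, seed = 1) {
  cfg <- list(alpha = as.numeric(alpha), batch_size = as.integer(batch_size),
              lambda = as.numeric(lambda), beta1 = as.numeric(beta1),
              beta2 = as.numeric(beta2), epsilon = as.numeric(epsilon),
              epochs = as.integer(epochs),
              bias_correction = isTRUE(bias_correction),
              seed = as.integer(seed))
  if (cfg$alpha <= 0) stop("alpha must be > 0")
  if (cfg$lambda < 0) stop("lambda must be >= 0")
  if (cfg$beta1 < 0 || cfg$beta1 >= 1 || cfg$beta2 < 0 || cfg$beta2 >= 1)
    stop("beta1 and beta2 must lie in [0, 1)")
  if (cfg$epsilon <= 0) stop("epsilon must be > 0")
  if (cfg$epochs < 1) stop("epochs must be >= 1")
  if (cfg$batch_size < 1) stop("batch_size must be >= 1")
  structure(cfg, class = "training_config")
}

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

#' Initialise network parameters
#'
#' Allocates all trainable parameters of the bidirectional LSTM classifier
#' with fan-based uniform (Glorot-style) scaling; biases start at zero
#' except the LSTM forget-gate bias, which starts at one. Repeated calls
#' with the same seed yield identical parameters.
#'
#' @param cfg a [network_config()].
#' @param seed integer seed.
#' @return A named list of parameter matrices/vectors: per direction
#'   (`fwd`, `bwd`) the input weights `Wx` (`n_axes x 4*hidden`), recurrent
#'   weights `Wh` (`hidden x 4*hidden`) and gate biases `b` (gate order:
#'   input, forget, cell, output); then `W1`/`b1` (fully connected,
#'   `2*hidden x fc_nodes`) and `W2`/`b2` (output map,
#'   `fc_nodes x n_classes`).
#' @export
bilstm_init <- function(cfg, seed = 1) {
  stopifnot(inherits(cfg, "network_config"))
  with_seed(seed, {
    H <- cfg$hidden; D <- cfg$n_axes; G <- 4L * H
    dir_init <- function() {
      b <- numeric(G)
      b[(H + 1):(2 * H)] <- 1  # forget gate
      list(Wx = glorot(D, G), Wh = glorot(H, G), b = b)
    }
    list(fwd = dir_init(), bwd = dir_init(),
         W1 = glorot(2 * H, cfg$fc_nodes), b1 = numeric(cfg$fc_nodes),
         W2 = glorot(cfg$fc_nodes, cfg$n_classes), b2 = numeric(cfg$n_classes))
  })
}

count_parameters <- function(params)
  sum(vapply(rapply(params, length, how = "unlist"), identity, numeric(1)))

sigmoid <- function(x) 1 / (1 + exp(-x))

# one-direction LSTM pass over x [B, D, N]; torder gives processing order.
# Returns final hidden state and (optionally) the caches needed for BPTT.
lstm_direction <- function(x, w, torder, keep_cache = FALSE) {
  B <- dim(x)[1]; H <- nrow(w$Wh); G <- ncol(w$Wx)
  stopifnot(G == 4 * H)
  h <- matrix(0, B, H); cst <- matrix(0, B, H)
  cache <- if (keep_cache) vector("list", length(torder))
  bmat <- matrix(w$b, B, G, byrow = TRUE)
  for (k in seq_along(torder)) {
    t <- torder[k]
    Xt <- matrix(x[, , t], nrow = B)
    z <- Xt %*% w$Wx + h %*% w$Wh + bmat
    i <- sigmoid(z[, 1:H, drop = FALSE])
    f <- sigmoid(z[, (H + 1):(2 * H), drop = FALSE])
    g <- tanh(z[, (2 * H + 1):(3 * H), drop = FALSE])
    o <- sigmoid(z[, (3 * H + 1):(4 * H), drop = FALSE])
    c_new <- f * cst + i * g
    tc <- tanh(c_new)
    h_new <- o * tc
    if (keep_cache)
      cache[[k]] <- list(Xt = Xt, h_prev = h, c_prev = cst,
                         i = i, f = f, g = g, o = o, tc = tc)
    h <- h_new; cst <- c_new
  }
  list(h_last = h, cache = cache)
}

# backward through one direction given the gradient of the loss wrt the
# final hidden state; returns parameter gradients
lstm_direction_backward <- function(w, cache, dh_last) {
  B <- nrow(dh_last); H <- ncol(dh_last)
  gWx <- matrix(0, nrow(w$Wx), ncol(w$Wx))
  gWh <- matrix(0, nrow(w$Wh), ncol(w$Wh))
  gb <- numeric(length(w$b))
  dh <- dh_last; dc <- matrix(0, B, H)
  for (k in rev(seq_along(cache))) {
    cc <- cache[[k]]
    do <- dh * cc$tc
    dc <- dc + dh * cc$o * (1 - cc$tc^2)
    di <- dc * cc$g
    df <- dc * cc$c_prev
    dg <- dc * cc$i
    dz <- cbind(di * cc$i * (1 - cc$i),
                df * cc$f * (1 - cc$f),
                dg * (1 - cc$g^2),
                do * cc$o * (1 - cc$o))
    gWx <- gWx + crossprod(cc$Xt, dz)
    gWh <- gWh + crossprod(cc$h_prev, dz)
    gb <- gb + colSums(dz)
    dh <- dz %*% t(w$Wh)
    dc <- dc * cc$f
  }
  list(Wx = gWx, Wh = gWh, b = gb)
}

as_batch_array <- function(x) {
  if (inherits(x, "event_set")) x <- x$traces
  if (is.matrix(x)) x <- array(x, c(1L, dim(x)))
  stopifnot(is.array(x), length(dim(x)) == 3L)
  x
}

#' Forward pass: class probabilities for a batch of traces
#'
#' Runs z-normalised traces through the bidirectional LSTM and returns the
#' softmax class probabilities. Each row is non-negative and sums to one;
#' the pass is independent across batch rows, so duplicated events yield
#' identical outputs and batch order is immaterial.
#'
#' @param params parameter list from [bilstm_init()] (or a fitted model's
#'   `$params`).
#' @param x a `3 x 100` matrix, an `[n, 3, 100]` array, or an
#'   [event_set()] of z-normalised traces.
#' @return An `n x 2` matrix of class probabilities with columns
#'   `VH`, `NH`.
#' @export
bilstm_forward <- function(params, x) {
  x <- as_batch_array(x)
  if (dim(x)[2] != nrow(params$fwd$Wx))
    stop("input has ", dim(x)[2], " axes; network expects ",
         nrow(params$fwd$Wx))
  N <- dim(x)[3]
  fw <- lstm_direction(x, params$fwd, seq_len(N))
  bw <- lstm_direction(x, params$bwd, rev(seq_len(N)))
  u <- cbind(fw$h_last, bw$h_last)
  hfc <- tanh(sweep(u %*% params$W1, 2, params$b1, `+`))
  logits <- sweep(hfc %*% params$W2, 2, params$b2, `+`)
  p <- softmax_rows(logits)
  colnames(p) <- c("VH", "NH")
  p
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# cross-entropy + L2 loss and full analytic gradients for one batch.
# y: integer class index (1 = VH, 2 = NH).
bilstm_loss_grads <- function(params, x, y, lambda = 0) {
  x <- as_batch_array(x)
  B <- dim(x)[1]; N <- dim(x)[3]
  H <- nrow(params$fwd$Wh)
  stopifnot(length(y) == B)
  fw <- lstm_direction(x, params$fwd, seq_len(N), keep_cache = TRUE)
  bw <- lstm_direction(x, params$bwd, rev(seq_len(N)), keep_cache = TRUE)
  u <- cbind(fw$h_last, bw$h_last)
  hfc <- tanh(sweep(u %*% params$W1, 2, params$b1, `+`))
  logits <- sweep(hfc %*% params$W2, 2, params$b2, `+`)
  p <- softmax_rows(logits)
  eps <- 1e-12
  ce <- -mean(log(pmax(p[cbind(seq_len(B), y)], eps)))
  l2 <- lambda * (sum(params$fwd$Wx^2) + sum(params$fwd$Wh^2) +
                  sum(params$bwd$Wx^2) + sum(params$bwd$Wh^2) +
                  sum(params$W1^2) + sum(params$W2^2))
  loss <- ce + l2

  Y <- matrix(0, B, ncol(p)); Y[cbind(seq_len(B), y)] <- 1
  dlogits <- (p - Y) / B
  gW2 <- crossprod(hfc, dlogits) + 2 * lambda * params$W2
  gb2 <- colSums(dlogits)
  dhfc <- dlogits %*% t(params$W2)
  da1 <- dhfc * (1 - hfc^2)
  gW1 <- crossprod(u, da1) + 2 * lambda * params$W1
  gb1 <- colSums(da1)
  du <- da1 %*% t(params$W1)
  gf <- lstm_direction_backward(params$fwd, fw$cache,
                                du[, 1:H, drop = FALSE])
  gb_ <- lstm_direction_backward(params$bwd, bw$cache,
                                 du[, (H + 1):(2 * H), drop = FALSE])
  gf$Wx <- gf$Wx + 2 * lambda * params$fwd$Wx
  gf$Wh <- gf$Wh + 2 * lambda * params$fwd$Wh
  gb_$Wx <- gb_$Wx + 2 * lambda * params$bwd$Wx
  gb_$Wh <- gb_$Wh + 2 * lambda * params$bwd$Wh
  list(loss = loss, ce = ce,
       grads = list(fwd = gf, bwd = gb_, W1 = gW1, b1 = gb1,
                    W2 = gW2, b2 = gb2),
       probs = p)
}
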