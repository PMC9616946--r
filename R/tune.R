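#' Hyperparameter search space
#'
#' The four tunable training parameters and their ranges: initial learning
#' rate in `[1e-2, 1]` (log scale), mini-batch size in `[64, 128]`
#' (integer), L2 regularization factor in `[1e-8, 1e-1]` (log scale) and
#' fully connected nodes in `[20, 100]` (integer).
#'
#' @param alpha,lambda numeric ranges (length 2, positive, searched on a
#'   log scale).
#' @param batch_size,fc_nodes integer ranges (length 2).
#' @return A list of class `hyper_space`.
#' @export
hyper_space <- function(alpha = c(1e-2, 1), batch_size = c(64, 128),
                        lambda = c(1e-8, 1e-1), fc_nodes = c(20, 100)) {
  chk <- function(r, nm) {
    if (length(r) != 2 || r[1] >= r[2]) stop(nm, " range must be ordered")
    as.numeric(r)
  }
  structure(list(alpha = chk(alpha, "alpha"),
                 batch_size = chk(batch_size, "batch_size"),
                 lambda = chk(lambda, "lambda"),
                 fc_nodes = chk(fc_nodes, "fc_nodes")),
            class = "hyper_space")
}

# map unit-cube coordinates to a concrete configuration and back
space_decode <- function(u, space) {
  logmap <- function(v, r) exp(log(r[1]) + v * (log(r[2]) - log(r[1])))
  linmap <- function(v, r) r[1] + v * (r[2] - r[1])
  list(alpha = logmap(u[1], space$alpha),
       batch_size = as.integer(round(linmap(u[2], space$batch_size))),
       lambda = logmap(u[3], space$lambda),
       fc_nodes = as.integer(round(linmap(u[4], space$fc_nodes))))
}

# squared-exponential GP posterior at candidate points
gp_posterior <- function(X, y, Xstar, lengthscale, sf2, noise = 1e-6) {
  k <- function(A, B) {
    d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * A %*% t(B)
    sf2 * exp(-pmax(d2, 0) / (2 * lengthscale^2))
  }
  K <- k(X, X) + diag(noise + 1e-10, nrow(X))
  L <- chol(K)
  alpha <- backsolve(L, forwardsolve(t(L), y))
  Ks <- k(Xstar, X)
  mu <- as.numeric(Ks %*% alpha)
  v <- forwardsolve(t(L), t(Ks))
  var <- pmax(sf2 - colSums(v^2), 1e-12)
  list(mu = mu, sd = sqrt(var))
}

gp_loglik <- function(X, y, lengthscale, sf2, noise = 1e-6) {
  d2 <- outer(rowSums(X^2), rowSums(X^2), `+`) - 2 * X %*% t(X)
  K <- sf2 * exp(-pmax(d2, 0) / (2 * lengthscale^2)) +
    diag(noise + 1e-10, nrow(X))
  L <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(L)) return(-Inf)
  a <- backsolve(L, forwardsolve(t(L), y))
  -0.5 * sum(y * a) - sum(log(diag(L))) - 0.5 * length(y) * log(2 * pi)
}

# expected improvement (minimisation) of candidates under the GP surrogate
expected_improvement <- function(mu, sd, best) {
  z <- (best - mu) / sd
  (best - mu) * stats::pnorm(z) + sd * stats::dnorm(z)
}

# fit GP on observed unit-cube points (lengthscale by marginal likelihood
# grid) and propose the EI-maximising candidate from a random candidate set
gp_propose <- function(U, y, n_cand = 512) {
  ybar <- mean(y); ysd <- stats::sd(y)
  if (!is.finite(ysd) || ysd == 0) ysd <- 1
  ys <- (y - ybar) / ysd
  lens <- c(0.1, 0.2, 0.3, 0.5, 1)
  ll <- vapply(lens, function(l) gp_loglik(U, ys, l, 1, 1e-4), numeric(1))
  len <- lens[which.max(ll)]
  cand <- matrix(stats::runif(n_cand * ncol(U)), n_cand, ncol(U))
  post <- gp_posterior(U, ys, cand, len, 1, 1e-4)
  ei <- expected_improvement(post$mu, post$sd, min(ys))
  cand[which.max(ei), ]
}

#' Bayesian hyperparameter optimization
#'
#' Minimises the validation classification error over the hyperparameter
#' space with a Gaussian-process surrogate: after a small random initial
#' design, each subsequent configuration is chosen by maximising the
#' expected improvement of the surrogate fitted to all observed
#' (configuration, validation error) pairs, then evaluated by actually
#' training the network. The configuration with the lowest observed
#' validation error is returned.
#'
#' @param x,y training data, as in [fit_bilstm()].
#' @param validation validation data, as in [fit_bilstm()]; the objective
#'   is the misclassification rate on this set.
#' @param space a [hyper_space()].
#' @param budget total number of objective evaluations (at least 5; the
#'   first `n_init` form the initial design).
#' @param n_init random initial-design size (default 5).
#' @param net base [network_config()]; `fc_nodes` is overridden per
#'   proposal.
#' @param cfg base [training_config()]; `alpha`, `batch_size`, `lambda`
#'   are overridden per proposal.
#' @param seed integer seed.
#' @return A list of class `bilstm_tune`: `best` (list with the winning
#'   `network_config`/`training_config` and its error), and `history`
#'   (data frame of all evaluated configurations with their validation
#'   errors, in evaluation order).
#' @export
tune_bilstm <- function(x, y = NULL, validation, space = hyper_space(),
                        budget = 40, n_init = 5, net = network_config(),
                        cfg = training_config(), seed = 1) {
  if (budget < 5) stop("budget must be >= 5 evaluations")
  if (budget < n_init) stop("budget must be at least the initial design size")
  d <- as_training_data(x, y)
  val <- as_training_data(validation)
  evaluate <- function(conf) {
    net_i <- network_config(net$n_axes, net$n_steps, net$hidden,
                            conf$fc_nodes, net$n_classes)
    cfg_i <- training_config(alpha = conf$alpha, batch_size = conf$batch_size,
                             lambda = conf$lambda, beta1 = cfg$beta1,
                             beta2 = cfg$beta2, epsilon = cfg$epsilon,
                             epochs = cfg$epochs,
                             bias_correction = cfg$bias_correction,
                             seed = cfg$seed)
    fit <- fit_bilstm(d, net = net_i, cfg = cfg_i)
    pred <- forward_chunked(fit$params, val$x)
    mean((pred[, 1] >= 0.5) != (val$y == 1L))
  }
  with_seed(seed, {
    U <- matrix(stats::runif(n_init * 4), n_init, 4)
    hist <- NULL
    for (t in seq_len(budget)) {
      u <- if (t <= n_init) U[t, ] else gp_propose(U, hist$error)
      if (t > n_init) U <- rbind(U, u)
      conf <- space_decode(u, space)
      err <- evaluate(conf)
      hist <- rbind(hist, data.frame(eval = t, alpha = conf$alpha,
                                     batch_size = conf$batch_size,
                                     lambda = conf$lambda,
                                     fc_nodes = conf$fc_nodes,
                                     error = err))
    }
    best_i <- which.min(hist$error)
    bc <- hist[best_i, ]
    best <- list(
      network = network_config(net$n_axes, net$n_steps, net$hidden,
                               bc$fc_nodes, net$n_classes),
      training = training_config(alpha = bc$alpha, batch_size = bc$batch_size,
                                 lambda = bc$lambda, beta1 = cfg$beta1,
                                 beta2 = cfg$beta2, epsilon = cfg$epsilon,
                                 epochs = cfg$epochs,
                                 bias_correction = cfg$bias_correction,
                                 seed = cfg$seed),
      error = bc$error)
    structure(list(best = best, history = hist), class = "bilstm_tune")
  })
}

#' @export
print.bilstm_tune <- function(x, ...) {
  b <- x$history[which.min(x$history$error), ]
  cat("Bayesian hyperparameter optimization (", nrow(x$history),
      " evaluations)\n", sep = "")
  cat(sprintf("  best: alpha %.4g, batch %d, lambda %.4g, fc %d  (val error %.4f)\n",
              b$alpha, b$batch_size, b$lambda, b$fc_nodes, b$error))
  invisible(x)
}
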