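#' Moving-average adaptive moment (Adam) update
#'
#' One optimizer step over an arbitrary nested list of parameter tensors,
#' implementing the update exactly as used for training:
#' \deqn{m_l = \beta_1 m_{l-1} + (1-\beta_1)\,\nabla E(\theta_l)}
#' \deqn{v_l = \beta_2 v_{l-1} + (1-\beta_2)\,[\nabla E(\theta_l)]^2}
#' \deqn{\theta_{l+1} = \theta_l - \alpha\, m_l / (\sqrt{v_l} + \epsilon)}
#' Note the moment estimates are \emph{not} bias-corrected in this default
#' form, which differs from the standard presentation of Adam; setting
#' `bias_correction = TRUE` in the [training_config()] divides `m` and `v`
#' by `1 - beta1^l` and `1 - beta2^l` before the update.
#'
#' @param params nested list of numeric parameter tensors.
#' @param grads gradients with the same nesting and shapes.
#' @param state optimizer state from [adam_init()] (per-parameter first
#'   moment `m`, second moment `v`, iteration counter `l`).
#' @param cfg a [training_config()] supplying `alpha`, `beta1`, `beta2`,
#'   `epsilon` and `bias_correction`.
#' @return A list with updated `params` and `state` (counter incremented).
#' @examples
#' cfg <- training_config(alpha = 0.1)
#' st <- adam_init(list(w = 0))
#' adam_step(list(w = 0), list(w = 1), st, cfg)$params$w  # approx -0.1
#' @export
adam_step <- function(params, grads, state, cfg) {
  stopifnot(inherits(cfg, "training_config"))
  l <- state$l + 1L
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- Map(walk, p, g, m, v)
      return(list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
                  v = lapply(out, `[[`, "v")))
    }
    if (any(!is.finite(g)))
      stop("training error: non-finite gradient encountered at iteration ", l)
    m <- cfg$beta1 * m + (1 - cfg$beta1) * g
    v <- cfg$beta2 * v + (1 - cfg$beta2) * g^2
    m_use <- m; v_use <- v
    if (cfg$bias_correction) {
      m_use <- m / (1 - cfg$beta1^l)
      v_use <- v / (1 - cfg$beta2^l)
    }
    p <- p - cfg$alpha * m_use / (sqrt(v_use) + cfg$epsilon)
    list(p = p, m = m, v = v)
  }
  out <- walk(params, grads, state$m, state$v)
  list(params = out$p, state = list(m = out$m, v = out$v, l = l))
}

#' @rdname adam_step
#' @export
adam_init <- function(params) {
  zero <- function(p) if (is.list(p)) lapply(p, zero) else p * 0
  list(m = zero(params), v = zero(params), l = 0L)
}
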