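#' @title The two-head LSTM policy/value network
#' @description The tuning agent is a single network with two output heads.
#'   A 300-value DVH observation passes through a dense tanh layer into an
#'   LSTM cell (default 32 units); the hidden state feeds an 18-way softmax
#'   policy head and an 18-way linear Q-value head. Because the agent sees
#'   only the DVH — not the current TPPs — the tuning task is a partially
#'   observed decision process and the LSTM memory (c, h) is a genuine third
#'   input alongside the DVH. Forward and backward passes are hand-written
#'   so that gradients with respect to *inputs* (needed for integrated
#'   gradients) and *parameters* (needed for training) come from the same
#'   audited code path. All ops are batched over columns.
#' @name network
NULL

#' Network size configuration
#'
#' @param input length of the DVH observation (default 300).
#' @param dense width of the dense tanh encoder (default 64).
#' @param hidden LSTM units (default 32).
#' @param actions number of discrete actions (default 18).
#' @return a named list.
#' @export
net_config <- function(input = 300L, dense = 64L, hidden = 32L, actions = 18L) {
  list(input = as.integer(input), dense = as.integer(dense),
       hidden = as.integer(hidden), actions = as.integer(actions))
}

#' Initialize network parameters
#'
#' Uniform fan-in scaled initialization; the forget-gate bias starts at +1
#' (a standard choice that keeps early memory open).
#'
#' @param config a [net_config()].
#' @param seed integer seed; identical seeds give identical parameters.
#' @param zero if TRUE all weights and biases are zero (useful for
#'   closed-form checks: zero logits give a uniform policy).
#' @return object of class `agent_params`: named list of matrices/vectors
#'   with the `config` attached.
#' @export
agent_init <- function(config = net_config(), seed = 1L, zero = FALSE) {
  mk <- function(nr, nc) {
    s <- 1 / sqrt(nc)
    if (zero) matrix(0, nr, nc) else matrix(stats::runif(nr * nc, -s, s), nr, nc)
  }
  vk <- function(n, val = 0) rep(val, n)
  with_seed(derive_seed(seed, "net-init"), {
    p <- list(
      Wd = mk(config$dense, config$input), bd = vk(config$dense),
      Wf = mk(config$hidden, config$dense), Uf = mk(config$hidden, config$hidden),
      bf = vk(config$hidden, if (zero) 0 else 1),
      Wi = mk(config$hidden, config$dense), Ui = mk(config$hidden, config$hidden),
      bi = vk(config$hidden),
      Wg = mk(config$hidden, config$dense), Ug = mk(config$hidden, config$hidden),
      bg = vk(config$hidden),
      Wo = mk(config$hidden, config$dense), Uo = mk(config$hidden, config$hidden),
      bo = vk(config$hidden),
      Wp = mk(config$actions, config$hidden), bp = vk(config$actions),
      Wq = mk(config$actions, config$hidden), bq = vk(config$actions)
    )
    structure(p, config = config, class = "agent_params")
  })
}

#' Fresh (zero) LSTM memory
#'
#' @param config a [net_config()].
#' @return list with numeric `c` and `h` vectors of length `config$hidden`.
#' @export
zero_memory <- function(config = net_config()) {
  list(c = numeric(config$hidden), h = numeric(config$hidden))
}

.sigmoid <- function(z) 1 / (1 + exp(-z))

.as_col <- function(x, n) {
  if (is.matrix(x)) x else matrix(x, nrow = n)
}

#' Forward pass of the two-head LSTM network
#'
#' Implements the cell
#' \deqn{f = \sigma(W_f a + U_f h + b_f),\ i = \sigma(W_i a + U_i h + b_i),}
#' \deqn{g = \tanh(W_g a + U_g h + b_g),\ o = \sigma(W_o a + U_o h + b_o),}
#' \deqn{c' = f \odot c + i \odot g,\quad h' = o \odot \tanh(c'),}
#' where `a = tanh(Wd x + bd)` encodes the DVH observation, followed by
#' `logits = Wp h' + bp` (softmax policy) and `q = Wq h' + bq`.
#'
#' @param params an [agent_init()] parameter set.
#' @param dvh DVH input: length-`input` vector or `input x K` matrix
#'   (columns are independent batch members).
#' @param memory list with `c` and `h` (vectors or `hidden x K` matrices).
#' @param keep_cache if TRUE the returned object carries the activations
#'   needed by [agent_backward()].
#' @return list with `probs` (`actions x K`), `q`, `memory` (new `c`, `h`)
#'   and optionally `cache`. For vector input the outputs are vectors.
#' @export
agent_forward <- function(params, dvh, memory, keep_cache = FALSE) {
  cfg <- attr(params, "config")
  vec_in <- !is.matrix(dvh)
  X <- .as_col(dvh, cfg$input)
  C <- .as_col(memory$c, cfg$hidden)
  H <- .as_col(memory$h, cfg$hidden)
  K <- ncol(X)
  if (any(!is.finite(X)) || any(!is.finite(C)) || any(!is.finite(H))) {
    stop("non-finite network input")
  }
  A <- tanh(params$Wd %*% X + params$bd)
  Fg <- .sigmoid(params$Wf %*% A + params$Uf %*% H + params$bf)
  Ig <- .sigmoid(params$Wi %*% A + params$Ui %*% H + params$bi)
  Gg <- tanh(params$Wg %*% A + params$Ug %*% H + params$bg)
  Og <- .sigmoid(params$Wo %*% A + params$Uo %*% H + params$bo)
  C2 <- Fg * C + Ig * Gg
  Tc <- tanh(C2)
  H2 <- Og * Tc
  logits <- params$Wp %*% H2 + params$bp
  # stable softmax per column
  lmax <- apply(logits, 2, max)
  el <- exp(sweep(logits, 2, lmax))
  probs <- sweep(el, 2, colSums(el), "/")
  q <- params$Wq %*% H2 + params$bq
  if (any(!is.finite(probs))) stop("non-finite policy output")
  out <- list(
    probs = if (vec_in) probs[, 1] else probs,
    q = if (vec_in) q[, 1] else q,
    memory = if (vec_in) list(c = C2[, 1], h = H2[, 1])
             else list(c = C2, h = H2)
  )
  if (keep_cache) {
    out$cache <- list(X = X, C = C, H = H, A = A, Fg = Fg, Ig = Ig, Gg = Gg,
                      Og = Og, C2 = C2, Tc = Tc, H2 = H2, probs = probs,
                      K = K)
  }
  out
}

#' Backward pass: gradients w.r.t. inputs and parameters
#'
#' Propagates upstream gradients on the policy logits and/or Q head back
#' through the cell. Input gradients are returned per batch column;
#' parameter gradients are summed over the batch.
#'
#' @param params an [agent_init()] parameter set.
#' @param cache the `cache` element of [agent_forward()] run with
#'   `keep_cache = TRUE`.
#' @param dlogits `actions x K` matrix (or vector) of gradients w.r.t. the
#'   policy logits; NULL for zero.
#' @param dq same for the Q head.
#' @param want_params if FALSE, parameter gradients are skipped (saves time
#'   in attribution loops).
#' @return list with `d_dvh`, `d_c`, `d_h` (matrices, columns = batch) and,
#'   if requested, `grads` (named like `params`).
#' @export
agent_backward <- function(params, cache, dlogits = NULL, dq = NULL,
                           want_params = TRUE) {
  cfg <- attr(params, "config")
  K <- cache$K
  zA <- matrix(0, cfg$actions, K)
  dL <- if (is.null(dlogits)) zA else .as_col(dlogits, cfg$actions)
  dQ <- if (is.null(dq)) zA else .as_col(dq, cfg$actions)
  dH2 <- crossprod(params$Wp, dL) + crossprod(params$Wq, dQ)
  dOg <- dH2 * cache$Tc
  dC2 <- dH2 * cache$Og * (1 - cache$Tc^2)
  dFg <- dC2 * cache$C
  dC_in <- dC2 * cache$Fg
  dIg <- dC2 * cache$Gg
  dGg <- dC2 * cache$Ig
  dzf <- dFg * cache$Fg * (1 - cache$Fg)
  dzi <- dIg * cache$Ig * (1 - cache$Ig)
  dzg <- dGg * (1 - cache$Gg^2)
  dzo <- dOg * cache$Og * (1 - cache$Og)
  dA <- crossprod(params$Wf, dzf) + crossprod(params$Wi, dzi) +
    crossprod(params$Wg, dzg) + crossprod(params$Wo, dzo)
  dH_in <- crossprod(params$Uf, dzf) + crossprod(params$Ui, dzi) +
    crossprod(params$Ug, dzg) + crossprod(params$Uo, dzo)
  dZd <- dA * (1 - cache$A^2)
  dX <- crossprod(params$Wd, dZd)
  out <- list(d_dvh = dX, d_c = dC_in, d_h = dH_in)
  if (want_params) {
    out$grads <- list(
      Wd = tcrossprod(dZd, cache$X), bd = rowSums(dZd),
      Wf = tcrossprod(dzf, cache$A), Uf = tcrossprod(dzf, cache$H),
      bf = rowSums(dzf),
      Wi = tcrossprod(dzi, cache$A), Ui = tcrossprod(dzi, cache$H),
      bi = rowSums(dzi),
      Wg = tcrossprod(dzg, cache$A), Ug = tcrossprod(dzg, cache$H),
      bg = rowSums(dzg),
      Wo = tcrossprod(dzo, cache$A), Uo = tcrossprod(dzo, cache$H),
      bo = rowSums(dzo),
      Wp = tcrossprod(dL, cache$H2), bp = rowSums(dL),
      Wq = tcrossprod(dQ, cache$H2), bq = rowSums(dQ)
    )
  }
  out
}

#' Gradient of one action's policy probability w.r.t. the three inputs
#'
#' Uses the softmax Jacobian row
#' \eqn{\partial p_j / \partial l_k = p_j(\delta_{jk} - p_k)} and the
#' network backward pass; batched over columns.
#'
#' @param params an [agent_init()] parameter set.
#' @param dvh,memory as in [agent_forward()] (may be batched).
#' @param action integer action index j.
#' @return list with `value` (p_j per column), `d_dvh`, `d_c`, `d_h`.
#' @export
policy_input_grad <- function(params, dvh, memory, action) {
  cfg <- attr(params, "config")
  fw <- agent_forward(params, dvh, memory, keep_cache = TRUE)
  P <- fw$cache$probs
  pj <- P[action, ]
  dlogits <- -P * rep(pj, each = nrow(P))
  dlogits[action, ] <- dlogits[action, ] + pj
  bw <- agent_backward(params, fw$cache, dlogits = dlogits,
                       want_params = FALSE)
  list(value = pj, d_dvh = bw$d_dvh, d_c = bw$d_c, d_h = bw$d_h)
}
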