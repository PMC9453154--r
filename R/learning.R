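# TD-error Q-learning loss and surrogate-gradient spatio-temporal
# backpropagation through the spiking network.

#' Temporal-difference error
#'
#' `delta = 0.5 * (r + gamma * max_a' Q(s', a') - Q(s, a))`; the bootstrap
#' term is dropped for terminal transitions.
#'
#' @param r Reward.
#' @param gamma Discount factor in `[0, 1]`.
#' @param q_next_max `max_a' Q(s', a')` from the target network.
#' @param q_sa Predicted Q(s, a).
#' @param terminal Logical (or 0/1): transition ended the episode.
#' @return The TD error `delta` (vectorized over its arguments).
#' @examples
#' td_error(1, 0.99, 2, 1)         # 0.5*(1 + 1.98 - 1) = 0.99
#' td_error(1, 0.99, 5, 0, TRUE)   # 0.5, bootstrap dropped
#' @export
td_error <- function(r, gamma, q_next_max, q_sa, terminal = FALSE) {
  if (!is.finite(gamma) || gamma < 0 || gamma > 1)
    stop("`gamma` must lie in [0, 1]")
  stopifnot(all(is.finite(r)), all(is.finite(q_next_max)), all(is.finite(q_sa)))
  0.5 * (r + gamma * q_next_max * (1 - as.numeric(terminal)) - q_sa)
}

#' Surrogate spike derivative
#'
#' The smooth, normalized bump `g(v) = 2*tau_s / (4 + (pi*tau_s*v)^2)`
#' substituted for the Heaviside derivative during backpropagation. By
#' default it is centered at the firing discontinuity (`v = u - v_th`); the
#' literal uncentered form (peak at `u = 0`) is available with
#' `centered = FALSE`. The function is even around its peak, strictly
#' positive, maximal value `tau_s / 2`, and integrates to 1 over the real
#' line (antiderivative `(1/pi) * atan(pi*tau_s*v/2) + 1/2`).
#'
#' @param u Membrane potential (vector/array).
#' @param v_th Firing threshold.
#' @param tau_s Sharpness constant, `> 0`; independent of the membrane time
#'   constant.
#' @param centered Center the bump at `v_th`.
#' @return Gradient values with the shape of `u`.
#' @export
surrogate_grad <- function(u, v_th = 0.5, tau_s = 2, centered = TRUE) {
  stopifnot(tau_s > 0)
  v <- if (centered) u - v_th else u
  2 * tau_s / (4 + (pi * tau_s * v)^2)
}

#' Surrogate spike primitive (relaxed spike)
#'
#' The antiderivative of [surrogate_grad()]: a smooth sigmoid in `(0, 1)`
#' used as a differentiable stand-in for the Heaviside spike when verifying
#' gradients by finite differences.
#'
#' @inheritParams surrogate_grad
#' @return Relaxed spike values in `(0, 1)` with the shape of `u`.
#' @export
surrogate_primitive <- function(u, v_th = 0.5, tau_s = 2, centered = TRUE) {
  stopifnot(tau_s > 0)
  v <- if (centered) u - v_th else u
  atan(pi * tau_s * v / 2) / pi + 0.5
}

#' Readout weight gradient
#'
#' For the time-averaged readout, the gradient of the TD loss with respect to
#' the selected action's weight row is `(1/T) * sum_t delta * O_t`; the other
#' action rows receive zero.
#'
#' @param delta TD error (scalar).
#' @param fc_spike_train Hidden-layer [spike_train()], `(T x n_hidden)`.
#' @param action Selected action index (1-based).
#' @param n_actions Number of actions (rows of the readout weight).
#' @return Gradient matrix `(n_actions x n_hidden)`.
#' @export
output_weight_grad <- function(delta, fc_spike_train, action, n_actions) {
  if (action < 1 || action > n_actions) stop("action index out of range")
  g <- matrix(0, n_actions, ncol(fc_spike_train))
  g[action, ] <- delta * colSums(unclass(fc_spike_train)) / nrow(fc_spike_train)
  g
}

# pbLN backward on one (units x batch) block.
# ddrive: dL/dy with y = lam_full*xhat + beta_full; `n_chan` channels are
# interleaved channel-fastest down each column, so channel sums reduce to a
# reshape + rowSums.
pbln_backward_mat <- function(ddrive, x, mu, sd, lam_full, n_chan, eps) {
  n <- nrow(x); B <- ncol(x)
  d <- sd + eps
  xc <- x - rep(mu, rep.int(n, B))
  inv_d <- rep(1 / d, rep.int(n, B))
  xhat <- xc * inv_d
  gx <- ddrive * xhat
  dim(gx) <- c(n_chan, (n %/% n_chan) * B)
  dlam <- rowSums(gx)
  gb <- ddrive + 0
  dim(gb) <- c(n_chan, (n %/% n_chan) * B)
  dbeta <- rowSums(gb)
  dxhat <- ddrive * lam_full
  a <- .colMeans(dxhat, n, B)
  b <- .colSums(dxhat * xc, n, B)
  s_safe <- pmax(sd, 1e-12)
  dx <- dxhat * inv_d -
    rep(a / d, rep.int(n, B)) -
    xc * rep(b / (n * s_safe * d^2), rep.int(n, B))
  list(dx = dx, dlam = dlam, dbeta = dbeta)
}

#' Backpropagation through layers and time
#'
#' Applies the chain rule backwards over the unrolled (layer, time step)
#' graph of a recorded forward pass: the surrogate derivative stands in for
#' `do/du` at every spike, the membrane recurrence contributes a factor
#' `alpha` between consecutive steps, and the reset pathway is detached
#' (gradients do not flow through the reset assignment) for the discrete
#' spiking model. pbLN scale/shift gradients flow through the normalization
#' statistics (mean and standard deviation treated as differentiable
#' functions of the PSP).
#'
#' For a forward pass recorded with `relaxed = TRUE` the backward instead
#' computes the exact gradient of the surrogate-relaxed network (including
#' the differentiable reset gate), which is what central finite differences
#' verify.
#'
#' @param net The [sdqn_network()] used for the forward pass.
#' @param fwd Result of `network_forward(..., record = TRUE)`.
#' @param dq Gradient of the loss with respect to the Q outputs
#'   (`n_actions x B` matrix or a vector for a single sample).
#' @return Named flat list of gradients: `<layer>.W`, `<layer>.lam`,
#'   `<layer>.beta`, `readout.W`, matching [net_params()].
#' @export
network_backward <- function(net, fwd, dq) {
  rec <- fwd$record
  if (is.null(rec)) stop("backward needs a forward record (record = TRUE)")
  T_len <- rec$T
  B <- rec$B
  if (is.vector(dq)) dq <- matrix(dq, ncol = 1L)
  stopifnot(nrow(dq) == net$n_actions, ncol(dq) == B)
  relaxed <- isTRUE(rec$relaxed)
  alpha <- net$lif$alpha
  v_th <- net$lif$v_th
  v_reset <- net$lif$v_reset
  L <- length(net$layers)

  grads <- net_params(net)
  grads <- lapply(grads, function(p) p * 0)

  # readout: q = (1/T) sum_t W o_t
  top <- rec$layers[[L]]$o
  dW_ro <- grads[["readout.W"]]
  for (t in seq_len(T_len)) dW_ro <- dW_ro + tcrossprod(dq, top[[t]])
  grads[["readout.W"]] <- dW_ro / T_len
  ro_contrib <- crossprod(net$readout$W, dq) / T_len   # dL/do_top at each t

  du_pre_next <- lapply(net$layers, function(ly) matrix(0, ly$n_units, B))

  for (t in seq.int(T_len, 1L)) {
    do_cur <- ro_contrib
    for (l in seq.int(L, 1L)) {
      ly <- net$layers[[l]]
      lr <- rec$layers[[l]]
      u_pre <- lr$u_pre[[t]]
      o <- lr$o[[t]]
      g <- surrogate_grad(u_pre, v_th, net$tau_s, net$centered_surrogate)
      gate <- if (relaxed) (1 - o) + (v_reset - u_pre) * g else (1 - o)
      du_pre <- do_cur * g + alpha * du_pre_next[[l]] * gate
      du_pre_next[[l]] <- du_pre
      ddrive <- (1 - alpha) * du_pre

      use_pbln <- rec$pbln && !is.null(ly$pbln)
      if (use_pbln) {
        col_t <- if (ly$pbln$per_step) min(t, ncol(ly$pbln$lam)) else 1L
        n_chan <- if (ly$type == "conv") ly$out_ch else ly$n_units
        pb <- pbln_backward_mat(ddrive, lr$x[[t]], lr$mu[[t]], lr$sd[[t]],
                                ly$pbln$lam[ly$chan, col_t], n_chan,
                                ly$pbln$eps)
        nm_l <- paste0(ly$name, ".lam"); nm_b <- paste0(ly$name, ".beta")
        grads[[nm_l]][, col_t] <- grads[[nm_l]][, col_t] + pb$dlam
        grads[[nm_b]][, col_t] <- grads[[nm_b]][, col_t] + pb$dbeta
        dx <- pb$dx
      } else {
        dx <- ddrive
      }

      s_in <- if (l == 1L) rec$input else rec$layers[[l - 1L]]$o[[t]]
      nm_w <- paste0(ly$name, ".W")
      if (ly$type == "conv") {
        cb <- conv_backward_mat(dx, s_in, ly, want_dx = (l > 1L))
        grads[[nm_w]] <- grads[[nm_w]] + cb$dW
        if (l > 1L) do_cur <- cb$dX
      } else {
        grads[[nm_w]] <- grads[[nm_w]] + tcrossprod(dx, s_in)
        if (l > 1L) do_cur <- crossprod(ly$W, dx)
      }
    }
  }
  grads
}

#' Flat named parameter list of a network
#'
#' Parameter paths are `<layer>.W`, `<layer>.lam`, `<layer>.beta` (pbLN
#' layers), and `readout.W`. Conv weights are in their `(in*k*k x out)`
#' matmul form; use [conv_weight_array()] semantics only internally.
#'
#' @param net An [sdqn_network()].
#' @return Named list of numeric arrays.
#' @export
net_params <- function(net) {
  out <- list()
  for (ly in net$layers) {
    out[[paste0(ly$name, ".W")]] <- ly$W
    if (!is.null(ly$pbln)) {
      out[[paste0(ly$name, ".lam")]] <- ly$pbln$lam
      out[[paste0(ly$name, ".beta")]] <- ly$pbln$beta
    }
  }
  out[["readout.W"]] <- net$readout$W
  out
}

#' Write a flat parameter list back into a network
#'
#' @param net An [sdqn_network()].
#' @param params Named list as produced by [net_params()].
#' @return The updated network.
#' @export
net_set_params <- function(net, params) {
  for (i in seq_along(net$layers)) {
    nm <- net$layers[[i]]$name
    net$layers[[i]]$W <- params[[paste0(nm, ".W")]]
    if (!is.null(net$layers[[i]]$pbln)) {
      net$layers[[i]]$pbln$lam <- params[[paste0(nm, ".lam")]]
      net$layers[[i]]$pbln$beta <- params[[paste0(nm, ".beta")]]
    }
  }
  net$readout$W <- params[["readout.W"]]
  net
}

#' Clip gradients to a global L2 norm
#'
#' @param grads Named gradient list.
#' @param max_norm Maximum global norm; `Inf` disables clipping.
#' @return The (possibly rescaled) gradient list.
#' @export
clip_global_norm <- function(grads, max_norm = 10) {
  if (!is.finite(max_norm)) return(grads)
  total <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  if (total > max_norm && total > 0)
    grads <- lapply(grads, function(g) g * (max_norm / total))
  grads
}

# --- Adam optimizer over flat parameter lists ------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_update <- function(params, grads, state, lr = 1e-4,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
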