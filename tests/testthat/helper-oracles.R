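# Shared oracles and fixture builders. Everything here is independent of the
# implementation paths it checks: brute-force loops, closed forms, finite
# differences on the relaxed network.

# Nested-loop valid cross-correlation, the conv oracle.
brute_conv <- function(x, warr, stride) {
  oc <- dim(warr)[1]; ic <- dim(warr)[2]; k <- dim(warr)[3]
  H <- dim(x)[2]; W <- dim(x)[3]
  oh <- (H - k) %/% stride + 1L
  ow <- (W - k) %/% stride + 1L
  out <- array(0, c(oc, oh, ow))
  for (o in seq_len(oc)) for (i in seq_len(oh)) for (j in seq_len(ow)) {
    s <- 0
    for (c in seq_len(ic)) for (a in seq_len(k)) for (b in seq_len(k))
      s <- s + warr[o, c, a, b] * x[c, (i - 1) * stride + a, (j - 1) * stride + b]
    out[o, i, j] <- s
  }
  out
}

# Central finite differences of the relaxed forward under the linear
# functional sum(cvec * q); the independent gradient oracle.
fd_gradients <- function(net, x, cvec, T, h = 1e-5) {
  J <- function(p)
    sum(cvec * network_forward(net_set_params(net, p), x, T = T,
                               relaxed = TRUE)$q)
  p0 <- net_params(net)
  out <- p0
  for (nm in names(p0)) {
    fd <- p0[[nm]] * 0
    for (i in seq_along(fd)) {
      pp <- p0
      pp[[nm]][i] <- pp[[nm]][i] + h
      f1 <- J(pp)
      pp[[nm]][i] <- pp[[nm]][i] - 2 * h
      f2 <- J(pp)
      fd[i] <- (f1 - f2) / (2 * h)
    }
    out[[nm]] <- fd
  }
  out
}

# Worst relative error of analytic relaxed-model gradients vs central
# finite differences, normalized by the overall gradient scale (per-tensor
# normalization would divide finite-difference roundoff by the near-zero
# magnitude of saturated parameters).
grad_check_error <- function(net, x, cvec, T) {
  fwd <- network_forward(net, x, T = T, record = TRUE, relaxed = TRUE)
  g <- network_backward(net, fwd, cvec)
  fd <- fd_gradients(net, x, cvec, T)
  scale <- max(abs(unlist(fd))) + 1e-8
  max(abs(unlist(g) - unlist(fd))) / scale
}

# Random small fully-connected spiking net (optionally pbLN-normalized),
# the population of the gradient-oracle sweep.
random_tiny_net <- function(seed) {
  set.seed(seed)
  n_in <- sample(3:6, 1)
  n_layers <- sample(1:3, 1)
  sizes <- sample(2:8, n_layers, replace = TRUE)
  sdqn_network(input_shape = n_in, n_actions = sample(2:4, 1),
               conv = list(), fc = sizes,
               pbln_fc = sample(c(TRUE, FALSE), 1),
               T = sample(1:4, 1),
               init = "gaussian", weight_sd = 0.6, seed = seed + 1000L)
}
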