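# Spiking convolutional / fully-connected layers, potential-based layer
# normalization (pbLN), and the time-averaged readout head.
#
# Internal layout convention: a layer activation is a numeric matrix
# (units x batch) whose unit ordering is channel-fastest, i.e. the flat index
# of element (c, i, j) is c + C*(i-1) + C*H*(j-1). An R array with
# dim = c(C, H, W) flattens to exactly this order, so as.vector()/array()
# convert between the two representations with no permutation.

#' Convolutional layer specification
#'
#' @param weight 4-d array `(out_channels, in_channels, k, k)` of kernel
#'   weights; finite.
#' @param stride Positive integer stride (no padding; valid cross-correlation).
#' @return An object of class `"conv_layer_spec"`.
#' @export
conv_layer_spec <- function(weight, stride = 1L) {
  stopifnot(is.array(weight), length(dim(weight)) == 4L, dim(weight)[3] == dim(weight)[4])
  if (anyNA(weight) || any(!is.finite(weight))) stop("conv weights must be finite")
  if (stride < 1) stop("`stride` must be >= 1")
  if (dim(weight)[3] < 1) stop("`kernel_size` must be >= 1")
  structure(list(out_channels = dim(weight)[1], in_channels = dim(weight)[2],
                 kernel_size = dim(weight)[3], stride = as.integer(stride),
                 weight = weight),
            class = "conv_layer_spec")
}

#' Fully-connected layer specification
#'
#' @param weight 2-d matrix `(out, in)`; finite.
#' @return An object of class `"fc_layer_spec"`.
#' @export
fc_layer_spec <- function(weight) {
  stopifnot(is.matrix(weight))
  if (anyNA(weight) || any(!is.finite(weight))) stop("fc weights must be finite")
  structure(list(weight = weight), class = "fc_layer_spec")
}

# Reshape a (out,in,k,k) kernel array into the (in*k*k x out) matmul form
# whose row order (c_in fastest, kernel row, kernel col) matches the im2col
# patch index built in build_conv_geometry().
conv_weight_matrix <- function(warr) {
  w <- aperm(warr, c(2L, 3L, 4L, 1L))          # (in, k, k, out)
  dim(w) <- c(prod(dim(w)[1:3]), dim(w)[4])
  w
}

conv_weight_array <- function(wmat, in_ch, k, out_ch) {
  w <- wmat
  dim(w) <- c(in_ch, k, k, out_ch)
  aperm(w, c(4L, 1L, 2L, 3L))
}

# Precompute the im2col gather index for a valid cross-correlation.
build_conv_geometry <- function(in_ch, in_h, in_w, k, stride) {
  if (in_h < k || in_w < k)
    stop(sprintf("input %dx%d smaller than kernel %d", in_h, in_w, k))
  out_h <- (in_h - k) %/% stride + 1L
  out_w <- (in_w - k) %/% stride + 1L
  ck2 <- in_ch * k * k
  npos <- out_h * out_w
  cvec <- rep(seq_len(in_ch), times = k * k)
  avec <- rep(rep(seq_len(k), each = in_ch), times = k)   # kernel row
  bvec <- rep(seq_len(k), each = in_ch * k)               # kernel col
  oi <- rep(seq_len(out_h), times = out_w)
  oj <- rep(seq_len(out_w), each = out_h)
  I <- outer(avec, (oi - 1L) * stride, `+`)               # ck2 x npos input rows
  J <- outer(bvec, (oj - 1L) * stride, `+`)
  idx <- cvec + in_ch * (I - 1L) + in_ch * in_h * (J - 1L)
  idx_vec <- as.vector(idx)
  # scatter operator for the input gradient: dX = scatter %*% dP
  scatter <- Matrix::sparseMatrix(i = idx_vec, j = seq_along(idx_vec), x = 1,
                                  dims = c(in_ch * in_h * in_w, length(idx_vec)))
  list(out_h = out_h, out_w = out_w, npos = npos, ck2 = ck2,
       idx = idx, idx_vec = idx_vec, scatter = scatter)
}

# Batched conv forward: X is (in_units x B); returns (out_units x B) with
# out ordering (c_out, oi, oj) channel-fastest.
conv_forward_mat <- function(X, ly) {
  B <- ncol(X)
  Xp <- X[ly$geom$idx_vec, , drop = FALSE]
  dim(Xp) <- c(ly$geom$ck2, ly$geom$npos * B)
  out <- crossprod(ly$W, Xp)                    # out_ch x (npos*B)
  dim(out) <- c(ly$out_ch * ly$geom$npos, B)
  out
}

# Backward of the conv matmul: returns gradient wrt weights (ck2 x out_ch)
# and wrt the layer input (in_units x B).
conv_backward_mat <- function(dY, X, ly, want_dx = TRUE) {
  B <- ncol(X)
  Xp <- X[ly$geom$idx_vec, , drop = FALSE]
  dim(Xp) <- c(ly$geom$ck2, ly$geom$npos * B)
  dim(dY) <- c(ly$out_ch, ly$geom$npos * B)
  dW <- tcrossprod(Xp, dY)                      # ck2 x out_ch
  dX <- NULL
  if (want_dx) {
    dP <- ly$W %*% dY                           # ck2 x (npos*B)
    dim(dP) <- c(ly$geom$ck2 * ly$geom$npos, B)
    dX <- as.matrix(ly$geom$scatter %*% dP)
  }
  list(dW = dW, dX = dX)
}

#' Convolutional post-synaptic potential
#'
#' Valid (unpadded) 2-d cross-correlation of the previous layer's spike map
#' with the kernel weights; linear in its input.
#'
#' @param prev_spikes Array `(in_channels, H, W)` of presynaptic spikes (any
#'   real values are accepted; spikes are the intended input).
#' @param spec A [conv_layer_spec()].
#' @return Array `(out_channels, H', W')` of PSP values.
#' @export
conv_psp <- function(prev_spikes, spec) {
  stopifnot(inherits(spec, "conv_layer_spec"))
  if (!is.array(prev_spikes) || length(dim(prev_spikes)) != 3L)
    stop("`prev_spikes` must be a 3-d array (channels, H, W)")
  d <- dim(prev_spikes)
  if (d[1] != spec$in_channels)
    stop(sprintf("input has %d channels, spec expects %d", d[1], spec$in_channels))
  geom <- build_conv_geometry(d[1], d[2], d[3], spec$kernel_size, spec$stride)
  ly <- list(geom = geom, W = conv_weight_matrix(spec$weight),
             out_ch = spec$out_channels)
  out <- conv_forward_mat(matrix(as.vector(prev_spikes), ncol = 1L), ly)
  array(out, dim = c(spec$out_channels, geom$out_h, geom$out_w))
}

#' Fully-connected post-synaptic potential
#'
#' The weighted sum of the previous layer's spikes, `W %*% o`.
#'
#' @param prev_spikes Numeric vector of presynaptic spikes.
#' @param spec A [fc_layer_spec()].
#' @return Numeric vector of PSP values, one per output neuron.
#' @export
fc_psp <- function(prev_spikes, spec) {
  stopifnot(inherits(spec, "fc_layer_spec"))
  if (length(prev_spikes) != ncol(spec$weight))
    stop(sprintf("length mismatch: %d spikes for %d inputs",
                 length(prev_spikes), ncol(spec$weight)))
  as.vector(spec$weight %*% prev_spikes)
}

#' pbLN learnable state
#'
#' One scale/shift pair per channel, initialized at
#' `lambda = v_th - v_reset`, `beta = v_reset`, so that a `+1` standard
#' deviation normalized input produces pre-leak drive exactly `v_th`
#' ("one sigma drives threshold").
#'
#' @param channels Number of channels normalized together.
#' @param params A [lif_params()] supplying `v_th` and `v_reset`.
#' @param eps Numerical-stability constant added to the standard deviation,
#'   `> 0`.
#' @return Object of class `"pbln_state"` with fields `lam`, `beta`, `eps`.
#' @export
pbln_state <- function(channels, params = lif_params(), eps = 1e-5) {
  stopifnot(channels >= 1, eps > 0)
  structure(list(lam = rep(params$v_th - params$v_reset, channels),
                 beta = rep(params$v_reset, channels),
                 eps = eps, channels = as.integer(channels)),
            class = "pbln_state")
}

#' Standardize a PSP map over all of its elements
#'
#' Computes `x_hat = (x - mean(x)) / (sd(x) + eps)` where mean and the
#' *population* standard deviation are taken jointly over every element of
#' `x` (all `C x H x W` values at this single time step). For a constant
#' input the standard deviation is zero and the output is all-zero, flagged
#' via `degenerate`.
#'
#' @param x Numeric array or vector with at least 2 elements.
#' @param eps Stability constant, `> 0` unless the input is known
#'   non-degenerate.
#' @return List with `x_hat`, `mean`, `sd` (population), and `degenerate`.
#' @examples
#' pbln_normalize(c(1, 2, 3, 4), eps = 0)$x_hat  # (x - 2.5)/sqrt(1.25)
#' @export
pbln_normalize <- function(x, eps = 1e-5) {
  H <- length(x)
  if (H < 2) stop("pbLN needs at least 2 elements (variance undefined)")
  m <- mean(x)
  xc <- x - m
  s <- sqrt(mean(xc^2))
  degenerate <- (s == 0)
  x_hat <- if (degenerate && eps == 0) xc * 0 else xc / (s + eps)
  list(x_hat = x_hat, mean = m, sd = s, degenerate = degenerate)
}

#' Per-channel affine transform of a normalized PSP map
#'
#' `lambda_c * x_hat + beta_c`, broadcast over spatial positions. At
#' initialization this maps a standardized input of +1 sd to `v_th`.
#'
#' @param x_hat Normalized array `(C, H, W)` or a vector with one element per
#'   channel.
#' @param state A [pbln_state()].
#' @return Scaled-and-shifted drive with the shape of `x_hat`.
#' @export
pbln_affine <- function(x_hat, state) {
  stopifnot(inherits(state, "pbln_state"))
  C <- state$channels
  if (is.array(x_hat) && length(dim(x_hat)) == 3L) {
    if (dim(x_hat)[1] != C)
      stop(sprintf("x_hat has %d channels, pbln state has %d", dim(x_hat)[1], C))
    chan <- rep(seq_len(C), times = prod(dim(x_hat)[2:3]))
    out <- state$lam[chan] * as.vector(x_hat) + state$beta[chan]
    array(out, dim = dim(x_hat))
  } else {
    if (length(x_hat) %% C != 0)
      stop(sprintf("length %d not a multiple of %d channels", length(x_hat), C))
    chan <- rep_len(seq_len(C), length(x_hat))
    state$lam[chan] * x_hat + state$beta[chan]
  }
}

#' LIF step with potential-based layer normalization
#'
#' Composes [pbln_normalize()], [pbln_affine()] and [lif_step()]: the raw PSP
#' is standardized over the layer, rescaled per channel, and used as the
#' input drive of the adapted membrane update
#' `u[t+1] = alpha*u[t] + (1-alpha)*(lambda*x_hat + beta)`. Spiking and reset
#' semantics are identical to [lif_step()].
#'
#' @param state A [neuron_state()].
#' @param raw_psp Numeric array/vector of un-normalized PSP values.
#' @param pbln A [pbln_state()].
#' @param params A [lif_params()].
#' @return As [lif_step()], plus the normalization `stats`.
#' @export
pbln_lif_step <- function(state, raw_psp, pbln, params) {
  nz <- pbln_normalize(raw_psp, pbln$eps)
  drive <- pbln_affine(nz$x_hat, pbln)
  st <- lif_step(state, as.vector(drive), params)
  st$stats <- nz[c("mean", "sd", "degenerate")]
  st
}

#' Readout specification
#'
#' @param weight Matrix `(n_actions, n_hidden)`.
#' @param T Time-window length, `>= 1`.
#' @return Object of class `"readout_spec"`.
#' @export
readout_spec <- function(weight, T) {
  stopifnot(is.matrix(weight), T >= 1)
  structure(list(weight = weight, T = as.integer(T)), class = "readout_spec")
}

#' Time-averaged Q-value readout
#'
#' `q_i = (1/T) * sum_t W[i, ] %*% O[t, ]` — a non-spiking linear head that
#' averages the weighted hidden spike train over the simulation window. `q`
#' depends on the train only through per-neuron spike counts.
#'
#' @param fc_spikes A [spike_train()] of shape `(T, n_hidden)`.
#' @param spec A [readout_spec()] with matching `T`.
#' @return Numeric vector of `n_actions` Q-values.
#' @export
readout_q <- function(fc_spikes, spec) {
  stopifnot(inherits(spec, "readout_spec"))
  if (nrow(fc_spikes) != spec$T)
    stop(sprintf("spike train has %d steps, readout expects T = %d",
                 nrow(fc_spikes), spec$T))
  as.vector(spec$weight %*% colSums(unclass(fc_spikes))) / spec$T
}

# ---------------------------------------------------------------------------
# Network construction

init_weight <- function(n_out, fan_in, n_total, init, weight_sd) {
  if (init == "uniform") {
    bound <- 1 / sqrt(fan_in)
    runif(n_total, -bound, bound)
  } else {
    rnorm(n_total, 0, weight_sd)
  }
}

#' Parse an architecture string
#'
#' Strings like `"c32k8-c64k4-c64k3"` name the convolutional stack (channels
#' and kernel per layer). Strides are supplied separately (the canonical DQN
#' values 4, 2, 1 by default).
#'
#' @param arch Architecture string.
#' @param strides Integer vector, one stride per conv layer.
#' @return List of `(out_channels, kernel, stride)` triples.
#' @export
parse_arch <- function(arch = "c32k8-c64k4-c64k3", strides = c(4L, 2L, 1L)) {
  parts <- strsplit(arch, "-", fixed = TRUE)[[1]]
  if (length(strides) != length(parts))
    stop("need one stride per conv layer")
  lapply(seq_along(parts), function(i) {
    m <- regmatches(parts[i], regexec("^c([0-9]+)k([0-9]+)$", parts[i]))[[1]]
    if (length(m) != 3) stop("cannot parse conv layer spec: ", parts[i])
    c(out = as.integer(m[2]), k = as.integer(m[3]), stride = as.integer(strides[i]))
  })
}

#' Build a spiking deep Q-network
#'
#' Constructs the layer stack: spiking conv layers (pbLN-normalized by
#' default), spiking fully-connected hidden layer(s), and a non-spiking
#' time-averaged linear readout producing one Q-value per action. The default
#' architecture is the DQN stack `c32k8-c64k4-c64k3` (strides 4, 2, 1, no
#' padding) on a 4x84x84 grayscale frame stack, followed by 512 hidden
#' neurons.
#'
#' @param input_shape `c(channels, H, W)` for pixel input, or a single number
#'   of features for a vector-input (conv-free) network.
#' @param n_actions Number of Q outputs (environment-driven).
#' @param conv List of `c(out_channels, kernel, stride)` triples (e.g. from
#'   [parse_arch()]); may be empty.
#' @param fc Integer vector of hidden fully-connected layer sizes.
#' @param lif A [lif_params()] shared by every spiking layer.
#' @param T Default simulation time-window length.
#' @param tau_s Surrogate-gradient sharpness constant (independent of the
#'   membrane `tau`).
#' @param pbln Apply pbLN in conv layers (the default placement).
#' @param pbln_fc Also normalize FC-layer PSPs (ablation switch).
#' @param pbln_per_step Learn separate `lambda_t, beta_t` per simulation step
#'   instead of sharing one pair across the window.
#' @param eps pbLN stability constant.
#' @param init `"uniform"` for scaled-uniform fan-in init
#'   `U(-1/sqrt(fan_in), 1/sqrt(fan_in))` (training default), or
#'   `"gaussian"` for i.i.d. zero-mean weights of sd `weight_sd`
#'   (the regime of the variance-propagation theory).
#' @param weight_sd Gaussian init standard deviation.
#' @param centered_surrogate Evaluate the surrogate at `u - v_th` (standard
#'   STBP reading); `FALSE` preserves the literal uncentered form.
#' @param seed Optional seed for weight initialization.
#' @return Object of class `"sdqn_network"`.
#' @export
sdqn_network <- function(input_shape = c(4, 84, 84), n_actions,
                         conv = parse_arch(), fc = 512,
                         lif = lif_params(), T = 16L, tau_s = 2,
                         pbln = TRUE, pbln_fc = FALSE, pbln_per_step = FALSE,
                         eps = 1e-5, init = c("uniform", "gaussian"),
                         weight_sd = 0.05, centered_surrogate = TRUE,
                         seed = NULL) {
  init <- match.arg(init)
  stopifnot(n_actions >= 1, T >= 1, tau_s > 0)
  if (!is.null(seed)) set.seed(seed)
  n_lam <- if (pbln_per_step) as.integer(T) else 1L

  layers <- list()
  if (length(input_shape) == 1L) {
    cur_units <- input_shape
    cur_shape <- NULL
    if (length(conv) > 0) stop("conv layers need a (C, H, W) input shape")
  } else {
    stopifnot(length(input_shape) == 3L)
    cur_shape <- input_shape
    cur_units <- prod(input_shape)
  }

  for (i in seq_along(conv)) {
    p <- conv[[i]]
    geom <- build_conv_geometry(cur_shape[1], cur_shape[2], cur_shape[3],
                                p[["k"]], p[["stride"]])
    W <- matrix(init_weight(p[["out"]], geom$ck2, geom$ck2 * p[["out"]],
                            init, weight_sd),
                geom$ck2, p[["out"]])
    ly <- list(type = "conv", name = paste0("conv", i),
               in_ch = cur_shape[1], in_h = cur_shape[2], in_w = cur_shape[3],
               out_ch = p[["out"]], k = p[["k"]], stride = p[["stride"]],
               geom = geom, W = W,
               n_units = p[["out"]] * geom$npos,
               chan = rep(seq_len(p[["out"]]), times = geom$npos))
    if (pbln) {
      ly$pbln <- list(lam = matrix(lif$v_th - lif$v_reset, p[["out"]], n_lam),
                      beta = matrix(lif$v_reset, p[["out"]], n_lam),
                      eps = eps, per_step = pbln_per_step)
    }
    layers[[length(layers) + 1L]] <- ly
    cur_shape <- c(p[["out"]], geom$out_h, geom$out_w)
    cur_units <- prod(cur_shape)
  }

  for (i in seq_along(fc)) {
    n_out <- fc[i]
    W <- matrix(init_weight(n_out, cur_units, n_out * cur_units, init, weight_sd),
                n_out, cur_units)
    ly <- list(type = "fc", name = paste0("fc", i),
               n_in = cur_units, n_units = n_out, W = W,
               chan = seq_len(n_out))
    if (pbln_fc) {
      ly$pbln <- list(lam = matrix(lif$v_th - lif$v_reset, n_out, n_lam),
                      beta = matrix(lif$v_reset, n_out, n_lam),
                      eps = eps, per_step = pbln_per_step)
    }
    layers[[length(layers) + 1L]] <- ly
    cur_units <- n_out
  }
  if (length(layers) == 0L) stop("network needs at least one spiking layer")

  Wro <- matrix(init_weight(n_actions, cur_units, n_actions * cur_units,
                            init, weight_sd),
                n_actions, cur_units)

  structure(list(layers = layers, readout = list(W = Wro),
                 lif = lif, T = as.integer(T), tau_s = tau_s,
                 n_actions = as.integer(n_actions),
                 input_shape = input_shape, pbln_on = TRUE,
                 centered_surrogate = centered_surrogate,
                 format_version = 1L),
            class = "sdqn_network")
}

#' @export
print.sdqn_network <- function(x, ...) {
  cat(sprintf("Spiking deep Q-network (T = %d, %d actions)\n", x$T, x$n_actions))
  cat(sprintf("  input: %s\n", paste(x$input_shape, collapse = "x")))
  for (ly in x$layers) {
    pb <- if (!is.null(ly$pbln)) " + pbLN" else ""
    if (ly$type == "conv")
      cat(sprintf("  %s: %d ch, k%d s%d -> %dx%dx%d%s\n", ly$name, ly$out_ch,
                  ly$k, ly$stride, ly$out_ch, ly$geom$out_h, ly$geom$out_w, pb))
    else
      cat(sprintf("  %s: %d -> %d%s\n", ly$name, ly$n_in, ly$n_units, pb))
  }
  cat(sprintf("  readout: %d -> %d (time-averaged)\n",
              ncol(x$readout$W), nrow(x$readout$W)))
  invisible(x)
}

# pbLN forward on a (units x batch) matrix; stats per column. `lam_full`
# and `beta_full` are the per-channel parameters already expanded to one
# value per unit (they recycle down columns).
pbln_forward_mat <- function(x, lam_full, beta_full, eps) {
  n <- nrow(x); B <- ncol(x)
  mu <- .colMeans(x, n, B)
  xc <- x - rep(mu, rep.int(n, B))
  sd <- sqrt(.colMeans(xc * xc, n, B))
  xhat <- xc / rep(sd + eps, rep.int(n, B))
  y <- xhat * lam_full + beta_full
  list(y = y, xhat = xhat, mu = mu, sd = sd)
}

as_input_matrix <- function(net, input) {
  n_in <- if (length(net$input_shape) == 1L) net$input_shape else prod(net$input_shape)
  if (is.array(input) && length(dim(input)) == 4L) {
    dim(input) <- c(prod(dim(input)[1:3]), dim(input)[4])
  } else if (is.array(input) && length(dim(input)) == 3L) {
    input <- matrix(as.vector(input), ncol = 1L)
  } else if (is.vector(input)) {
    input <- matrix(input, ncol = 1L)
  }
  if (nrow(input) != n_in)
    stop(sprintf("input has %d features, network expects %d", nrow(input), n_in))
  if (anyNA(input) || any(!is.finite(input))) stop("input frames must be finite")
  input
}

#' Forward pass of the spiking deep Q-network
#'
#' The same real-valued frame array is injected as the PSP drive of the first
#' conv layer at every one of the `T` simulation steps (constant-current
#' encoding); membrane states start fresh at `v_reset`; hidden spikes are
#' averaged by the linear readout into Q-values.
#'
#' @param net An [sdqn_network()].
#' @param input Frame array `(C, H, W)`, a batch `(C, H, W, B)`, a feature
#'   vector, or a `(features x B)` matrix.
#' @param T Time-window length (defaults to the network's `T`).
#' @param pbln Use pbLN where the network carries it; set `FALSE` to run the
#'   same weights as a vanilla (un-normalized) SDQN for paired comparisons.
#' @param record Keep the full per-layer, per-step record of potentials and
#'   spikes (needed by the backward pass and the diagnostics).
#' @param relaxed Replace the Heaviside spike by its smooth surrogate
#'   primitive (the arctan sigmoid whose derivative is the surrogate
#'   gradient). Used by gradient verification; spikes are then continuous in
#'   `(0, 1)`.
#' @return List with `q` (`n_actions x B` matrix; a vector for a single
#'   input), and when `record = TRUE`: `record` (internal structure consumed
#'   by [network_backward()]) and `spike_trains` (per-layer [spike_train()]s,
#'   single-sample inputs only).
#' @export
network_forward <- function(net, input, T = net$T, pbln = TRUE,
                            record = FALSE, relaxed = FALSE) {
  X <- as_input_matrix(net, input)
  single <- ncol(X) == 1L && (is.null(dim(input)) || length(dim(input)) != 4L)
  B <- ncol(X)
  alpha <- net$lif$alpha
  v_th <- net$lif$v_th
  v_reset <- net$lif$v_reset
  L <- length(net$layers)

  u <- lapply(net$layers, function(ly) matrix(v_reset, ly$n_units, B))
  qacc <- matrix(0, net$n_actions, B)
  rec <- if (record) {
    list(T = T, B = B, input = X, pbln = pbln, relaxed = relaxed,
         layers = lapply(seq_len(L), function(i)
           list(o = vector("list", T), u_pre = vector("list", T),
                x = vector("list", T), mu = vector("list", T),
                sd = vector("list", T))))
  } else NULL

  for (t in seq_len(T)) {
    s <- X
    for (l in seq_len(L)) {
      ly <- net$layers[[l]]
      x <- if (ly$type == "conv") conv_forward_mat(s, ly) else ly$W %*% s
      use_pbln <- pbln && !is.null(ly$pbln)
      if (use_pbln) {
        col_t <- if (ly$pbln$per_step) min(t, ncol(ly$pbln$lam)) else 1L
        pb <- pbln_forward_mat(x, ly$pbln$lam[ly$chan, col_t],
                               ly$pbln$beta[ly$chan, col_t], ly$pbln$eps)
        drive <- pb$y
      } else {
        drive <- x
      }
      u_pre <- alpha * u[[l]] + (1 - alpha) * drive
      o <- if (relaxed) surrogate_primitive(u_pre, v_th, net$tau_s,
                                            centered = net$centered_surrogate)
           else (u_pre >= v_th) + 0
      u[[l]] <- u_pre * (1 - o) + v_reset * o
      if (record) {
        rec$layers[[l]]$o[[t]] <- o
        rec$layers[[l]]$u_pre[[t]] <- u_pre
        if (use_pbln) {
          rec$layers[[l]]$x[[t]] <- x
          rec$layers[[l]]$mu[[t]] <- pb$mu
          rec$layers[[l]]$sd[[t]] <- pb$sd
        }
      }
      s <- o
    }
    qacc <- qacc + net$readout$W %*% s
  }
  q <- qacc / T

  out <- list(q = if (single) as.vector(q) else q)
  if (record) {
    out$record <- rec
    if (B == 1L && !relaxed) {
      out$spike_trains <- lapply(rec$layers, function(lr)
        spike_train(t(vapply(lr$o, as.vector,
                             numeric(length(lr$o[[1]]))))))
      names(out$spike_trains) <- vapply(net$layers, `[[`, "", "name")
    }
  }
  out
}
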