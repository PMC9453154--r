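test_that("TD error follows the half-scaled rule and drops terminal bootstrap", {
  expect_equal(td_error(1, 0.99, 2, 1), 0.99)
  expect_equal(td_error(0, 0.9, q_next_max = 1 / 0.9, q_sa = 1), 0)
  expect_equal(td_error(1, 0.99, 5, 0, terminal = TRUE), 0.5)
  expect_error(td_error(1, 1.2, 0, 0), "gamma")
  expect_error(td_error(1, -0.1, 0, 0), "gamma")
})

test_that("surrogate gradient: peak, symmetry, unit mass", {
  v_th <- 0.5
  for (tau_s in c(0.5, 2, 5)) {
    expect_equal(surrogate_grad(v_th, v_th, tau_s), tau_s / 2)
    d <- seq(0.05, 2, by = 0.3)
    expect_equal(surrogate_grad(v_th + d, v_th, tau_s),
                 surrogate_grad(v_th - d, v_th, tau_s))
    expect_true(all(surrogate_grad(rnorm(50), v_th, tau_s) > 0))
    mass <- stats::integrate(function(u) surrogate_grad(u, v_th, tau_s),
                             -Inf, Inf)$value
    expect_equal(mass, 1, tolerance = 1e-6)
  }
  # primitive really is the antiderivative
  u <- seq(-1, 2, by = 0.01)
  num <- diff(surrogate_primitive(u, 0.5, 2)) / diff(u)
  expect_equal(num, surrogate_grad((u[-1] + u[-length(u)]) / 2, 0.5, 2),
               tolerance = 1e-4)
  # uncentered literal form peaks at u = 0
  expect_equal(surrogate_grad(0, 0.5, 2, centered = FALSE), 1)
})

test_that("readout weight gradient averages delta-weighted spikes", {
  o <- matrix(1, 4, 5)
  g <- output_weight_grad(1, spike_train(o), action = 2, n_actions = 3)
  expect_equal(g[2, ], rep(1, 5))
  expect_true(all(g[c(1, 3), ] == 0))
  expect_true(all(output_weight_grad(2, spike_train(matrix(0, 4, 5)), 1, 3) == 0))
  set.seed(12)
  o <- matrix(rbinom(20, 1, 0.5), 4, 5)
  g <- output_weight_grad(0.7, spike_train(o), 1, 2)
  expect_equal(g[1, ], 0.7 * colMeans(o))
  expect_error(output_weight_grad(1, spike_train(o), 4, 3), "range")
})

test_that("a 2-step scalar chain matches the symbolic hand expansion", {
  # single input, single neuron, T = 2, no pbLN, relaxed spike; the loss is
  # J = c * q with q = (o1 + o2)/2 * w_ro.
  p <- lif_params(tau = 2, v_th = 0.5, v_reset = 0)
  net <- sdqn_network(input_shape = 1, n_actions = 1, conv = list(), fc = 1,
                      T = 2, lif = p, init = "gaussian", weight_sd = 1,
                      seed = 99)
  w <- 0.8; wro <- 1.3; x <- 0.9
  pr <- net_params(net)
  pr[["fc1.W"]][1] <- w; pr[["readout.W"]][1] <- wro
  net <- net_set_params(net, pr)
  fwd <- network_forward(net, x, record = TRUE, relaxed = TRUE)
  g <- network_backward(net, fwd, 1)
  # hand expansion
  S <- function(u) surrogate_primitive(u, p$v_th, net$tau_s)
  G <- function(u) surrogate_grad(u, p$v_th, net$tau_s)
  a <- p$alpha
  u1 <- (1 - a) * w * x
  o1 <- S(u1)
  u1s <- u1 * (1 - o1)                           # differentiable reset
  u2 <- a * u1s + (1 - a) * w * x
  o2 <- S(u2)
  du1_dw <- (1 - a) * x
  do1_dw <- G(u1) * du1_dw
  du1s_dw <- du1_dw * (1 - o1) - u1 * do1_dw
  du2_dw <- a * du1s_dw + (1 - a) * x
  do2_dw <- G(u2) * du2_dw
  expect_equal(as.numeric(g[["fc1.W"]]), wro * (do1_dw + do2_dw) / 2,
               tolerance = 1e-12)
  expect_equal(as.numeric(g[["readout.W"]]), (o1 + o2) / 2, tolerance = 1e-12)
})

test_that("analytic BPTT gradients match finite differences on small nets", {
  # a condensed sweep; the 100-network version runs in the acceptance suite
  for (seed in 1:10) {
    net <- random_tiny_net(seed)
    set.seed(seed + 500)
    x <- runif(net$input_shape)
    cvec <- rnorm(net$n_actions)
    expect_lt(grad_check_error(net, x, cvec, net$T), 1e-4)
  }
  # conv + pbLN case
  net <- sdqn_network(input_shape = c(2, 6, 6), n_actions = 2,
                      conv = list(c(out = 3, k = 3, stride = 1)), fc = 4,
                      pbln = TRUE, T = 3, init = "gaussian", weight_sd = 0.4,
                      seed = 77)
  set.seed(78)
  x <- array(runif(72), c(2, 6, 6))
  expect_lt(grad_check_error(net, x, rnorm(2), 3), 1e-4)
  # per-step pbLN parameters case
  netp <- sdqn_network(input_shape = 5, n_actions = 2, conv = list(), fc = 4,
                       pbln_fc = TRUE, pbln_per_step = TRUE, T = 3,
                       init = "gaussian", weight_sd = 0.6, seed = 79)
  set.seed(80)
  expect_lt(grad_check_error(netp, runif(5), rnorm(2), 3), 1e-4)
})

test_that("zero loss gradient yields exactly zero parameter gradients", {
  net <- random_tiny_net(3)
  set.seed(501)
  fwd <- network_forward(net, runif(net$input_shape), record = TRUE)
  g <- network_backward(net, fwd, rep(0, net$n_actions))
  expect_true(all(vapply(g, function(x) all(x == 0), TRUE)))
})

test_that("gradient clipping rescales to the requested global norm", {
  g <- list(a = matrix(3, 2, 2), b = rep(4, 3))
  total <- sqrt(sum(unlist(g)^2))
  gc <- clip_global_norm(g, max_norm = 1)
  expect_equal(sqrt(sum(unlist(gc)^2)), 1)
  expect_identical(clip_global_norm(g, Inf), g)
  expect_identical(clip_global_norm(g, 100), g)
})

test_that("200 Adam steps on a fixed synthetic batch halve the TD loss", {
  set.seed(41)
  net <- sdqn_network(input_shape = 8, n_actions = 3, conv = list(),
                      fc = c(12, 8), pbln_fc = TRUE, T = 4,
                      init = "gaussian", weight_sd = 0.5, seed = 41)
  B <- 16
  states <- matrix(runif(8 * B), 8, B)
  actions <- sample(1:3, B, replace = TRUE)
  y <- runif(B, -1, 1)                 # fixed targets
  params <- net_params(net)
  opt <- sdqn:::adam_init(params)
  losses <- numeric(200)
  for (it in 1:200) {
    fwd <- network_forward(net, states, record = TRUE)
    q_sa <- fwd$q[cbind(actions, seq_len(B))]
    losses[it] <- mean((y - q_sa)^2)
    dq <- matrix(0, 3, B)
    dq[cbind(actions, seq_len(B))] <- -2 * (y - q_sa) / B
    g <- network_backward(net, fwd, dq)
    upd <- sdqn:::adam_update(params, g, opt, lr = 5e-3)
    params <- upd$params; opt <- upd$state
    net <- net_set_params(net, params)
  }
  expect_lt(losses[200], 0.5 * losses[1])
})
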