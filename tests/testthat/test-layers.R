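test_that("conv PSP matches the nested-loop cross-correlation oracle", {
  set.seed(5)
  cases <- list(list(ic = 1, oc = 1, k = 3, s = 1, H = 8),
                list(ic = 2, oc = 3, k = 3, s = 1, H = 8),
                list(ic = 2, oc = 2, k = 4, s = 2, H = 10))
  for (cs in cases) {
    W <- array(rnorm(cs$oc * cs$ic * cs$k^2), c(cs$oc, cs$ic, cs$k, cs$k))
    x <- array(rbinom(cs$ic * cs$H^2, 1, 0.5), c(cs$ic, cs$H, cs$H))
    got <- conv_psp(x, conv_layer_spec(W, cs$s))
    want <- brute_conv(x, W, cs$s)
    expect_lt(max(abs(got - want)) / (max(abs(want)) + 1e-12), 1e-10)
  }
})

test_that("conv PSP degenerate structure: zeros, 1x1 identity, shape errors", {
  W1 <- array(2.5, c(1, 1, 1, 1))
  x <- array(rbinom(25, 1, 0.5), c(1, 5, 5))
  expect_equal(conv_psp(x, conv_layer_spec(W1, 1))[1, , ], 2.5 * x[1, , ])
  expect_true(all(conv_psp(array(0, c(1, 5, 5)), conv_layer_spec(W1, 1)) == 0))
  W3 <- array(1, c(1, 2, 3, 3))
  expect_error(conv_psp(x, conv_layer_spec(W3, 1)), "channels")
  expect_error(conv_layer_spec(array(NA_real_, c(1, 1, 2, 2))), "finite")
})

test_that("conv and fc PSPs are linear in their spike inputs", {
  set.seed(6)
  W <- array(rnorm(2 * 1 * 3 * 3), c(2, 1, 3, 3))
  spec <- conv_layer_spec(W, 1)
  a <- array(runif(36), c(1, 6, 6)); b <- array(runif(36), c(1, 6, 6))
  expect_equal(conv_psp(a + 2 * b, spec), conv_psp(a, spec) + 2 * conv_psp(b, spec))
  Wf <- matrix(rnorm(12), 3, 4)
  fspec <- fc_layer_spec(Wf)
  u <- runif(4); v <- runif(4)
  expect_equal(fc_psp(u + 3 * v, fspec), fc_psp(u, fspec) + 3 * fc_psp(v, fspec))
})

test_that("fc PSP equals the explicit summation and handles one-hots", {
  set.seed(7)
  W <- matrix(rnorm(15), 3, 5)
  spec <- fc_layer_spec(W)
  o <- rbinom(5, 1, 0.5)
  want <- vapply(1:3, function(i) sum(W[i, ] * o), numeric(1))
  expect_equal(fc_psp(o, spec), want)
  onehot <- c(0, 0, 1, 0, 0)
  expect_equal(fc_psp(onehot, spec), W[, 3])
  expect_equal(fc_psp(rep(0, 5), spec), rep(0, 3))
  expect_error(fc_psp(rep(1, 4), spec), "mismatch")
})

test_that("pbln_normalize matches hand arithmetic and its contracts", {
  # flat example, population variance
  nz <- pbln_normalize(c(1, 2, 3, 4), eps = 0)
  expect_equal(nz$mean, 2.5)
  expect_equal(nz$sd, sqrt(1.25))
  expect_equal(nz$x_hat, (c(1, 2, 3, 4) - 2.5) / sqrt(1.25))
  # already standardized input is (nearly) fixed
  x <- c(-1, 1)
  expect_equal(pbln_normalize(x, eps = 0)$x_hat, x)
  # degenerate constant input
  cz <- pbln_normalize(rep(3, 10))
  expect_true(cz$degenerate)
  expect_true(all(cz$x_hat == 0))
  expect_error(pbln_normalize(5), "2 elements")
  # mean/variance contracts on random arrays
  set.seed(8)
  eps <- 1e-5
  for (i in 1:200) {
    x <- rnorm(sample(10:200, 1), sd = runif(1, 0.1, 4))
    nz <- pbln_normalize(x, eps = eps)
    expect_lt(abs(mean(nz$x_hat)), 1e-6)
    target_var <- (nz$sd / (nz$sd + eps))^2
    expect_lt(abs(mean(nz$x_hat^2) - target_var), 1e-6)
  }
})

test_that("pbln_affine broadcasts per channel and checks shapes", {
  p <- lif_params(v_th = 0.5, v_reset = 0)
  st <- pbln_state(2, p)
  expect_equal(st$lam, c(0.5, 0.5))
  expect_equal(st$beta, c(0, 0))
  # identity when lam = 1, beta = 0
  st1 <- st; st1$lam <- c(1, 1)
  xh <- array(rnorm(2 * 3 * 3), c(2, 3, 3))
  expect_equal(pbln_affine(xh, st1), xh)
  # at init: 0.5 * x_hat
  expect_equal(pbln_affine(xh, st), 0.5 * xh)
  # constant shift
  st2 <- st; st2$lam <- c(2, 2); st2$beta <- c(-1, -1)
  expect_true(all(pbln_affine(array(0, c(2, 2, 2)), st2) == -1))
  st3 <- pbln_state(3, p)
  expect_error(pbln_affine(xh, st3), "channels")
})

test_that("pbln_lif_step equals the explicit composition", {
  p <- lif_params(tau = 2, v_th = 0.5, v_reset = 0)
  pb <- pbln_state(4, p)
  set.seed(9)
  x <- rnorm(4, sd = 2)
  s <- neuron_state(4, p)
  got <- pbln_lif_step(s, x, pb, p)
  nz <- pbln_normalize(x, pb$eps)
  want <- lif_step(s, pbln_affine(nz$x_hat, pb), p)
  expect_equal(got$state$u, want$state$u)
  expect_equal(got$spikes, want$spikes)
  # constant raw input: affine output is beta everywhere
  gotc <- pbln_lif_step(s, rep(2, 4), pb, p)
  wantc <- lif_step(s, rep(pb$beta[1], 4), p)
  expect_equal(gotc$state$u, wantc$state$u)
  # a +2 sd normalized input from rest is supra-threshold in one step
  # when alpha <= 0.5: drive = v_reset + 2(v_th - v_reset) = 1,
  # u' = 0.5 * 1 = 0.5 >= v_th
  xh2 <- c(2, rep(-2/3, 3))          # mean 0, population sd handled below
  drive <- pbln_affine(xh2, pb)
  st2 <- lif_step(neuron_state(4, p), drive, p)
  expect_equal(st2$spikes[1], 1)
})

test_that("readout averages weighted spike counts and checks T", {
  set.seed(10)
  W <- matrix(rnorm(3 * 6), 3, 6)
  spec <- readout_spec(W, T = 4)
  o <- matrix(rbinom(24, 1, 0.4), 4, 6)
  st <- spike_train(o)
  expect_equal(readout_q(st, spec), as.vector(W %*% colSums(o)) / 4)
  # silent train
  expect_equal(readout_q(spike_train(matrix(0, 4, 6)), spec), rep(0, 3))
  # neuron j always firing, others silent -> column j
  oj <- matrix(0, 4, 6); oj[, 3] <- 1
  expect_equal(readout_q(spike_train(oj), spec), W[, 3])
  # permuting spike times changes nothing
  operm <- o[c(3, 1, 4, 2), ]
  expect_equal(readout_q(spike_train(operm), spec), readout_q(st, spec))
  expect_error(readout_q(spike_train(matrix(0, 3, 6)), spec), "T = 4")
})

test_that("network forward: zero frames, T = 1, and batch consistency", {
  net <- sdqn_network(input_shape = c(1, 12, 12), n_actions = 3,
                      conv = list(c(out = 2, k = 3, stride = 2)), fc = 5,
                      T = 4, seed = 21)
  # zero frames with pbLN off and v_reset = 0: nothing ever fires
  z <- array(0, c(1, 12, 12))
  fwd <- network_forward(net, z, pbln = FALSE, record = TRUE)
  expect_equal(fwd$q, rep(0, 3))
  expect_true(all(vapply(fwd$spike_trains, function(s) all(s == 0), TRUE)))
  # T = 1 equals single-step weighted spikes
  x <- array(runif(144), c(1, 12, 12))
  f1 <- network_forward(net, x, T = 1, record = TRUE)
  o1 <- unclass(f1$spike_trains$fc1)[1, ]
  expect_equal(f1$q, as.vector(net$readout$W %*% o1))
  # a batch forward equals per-sample forwards
  X <- array(runif(144 * 3), c(1, 12, 12, 3))
  fb <- network_forward(net, X)
  for (b in 1:3)
    expect_equal(fb$q[, b], network_forward(net, array(X[, , , b], c(1, 12, 12)))$q)
})

test_that("with pbLN off, deep layers of a random DQN-style net fall silent", {
  # small-scale version of the depth experiment: the acceptance suite runs
  # the full architecture
  net <- sdqn_network(input_shape = c(2, 24, 24), n_actions = 4,
                      conv = list(c(out = 8, k = 5, stride = 2),
                                  c(out = 8, k = 3, stride = 1)),
                      fc = 16, T = 8, seed = 31)
  set.seed(31)
  x <- array(runif(2 * 24 * 24), c(2, 24, 24))
  off <- network_forward(net, x, pbln = FALSE, record = TRUE)
  on <- network_forward(net, x, pbln = TRUE, record = TRUE)
  ff_off <- vapply(off$spike_trains, firing_fraction, numeric(1))
  ff_on <- vapply(on$spike_trains, firing_fraction, numeric(1))
  expect_lte(ff_off[["conv2"]], ff_off[["conv1"]])
  expect_gt(ff_on[["conv2"]], ff_off[["conv2"]])
})

test_that("architecture strings parse to the canonical stack", {
  a <- parse_arch("c32k8-c64k4-c64k3", c(4, 2, 1))
  expect_length(a, 3)
  expect_equal(a[[1]], c(out = 32, k = 8, stride = 4))
  expect_equal(a[[3]], c(out = 64, k = 3, stride = 1))
  expect_error(parse_arch("c32k8-bogus", c(4, 2)), "parse")
  expect_error(parse_arch("c32k8", c(4, 2)), "stride")
})
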