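# Deep Q-learning orchestration around the spiking network: replay buffer,
# epsilon-greedy behaviour policy, target network, Adam updates.

#' Replay buffer
#'
#' A fixed-capacity ring of transitions. Frames are quantized to 8-bit
#' (0..255) for storage, the standard DQN memory layout; catch frames are
#' binary so the round trip is lossless.
#'
#' @param capacity Maximum number of transitions; oldest evicted first.
#' @param state_size Flattened state length.
#' @return Object of class `"replay_buffer"`.
#' @export
replay_buffer <- function(capacity, state_size) {
  stopifnot(capacity >= 1, state_size >= 1)
  b <- new.env(parent = baseenv())   # baseenv so in-place subassignment
  b$capacity <- as.integer(capacity) # via evalq() can resolve `[<-`
  b$state_size <- as.integer(state_size)
  b$s <- matrix(as.raw(0), state_size, capacity)
  b$s2 <- matrix(as.raw(0), state_size, capacity)
  b$a <- integer(capacity)
  b$r <- numeric(capacity)
  b$terminal <- logical(capacity)
  b$size <- 0L
  b$head <- 0L      # next write position - 1 (0-based)
  class(b) <- "replay_buffer"
  b
}

#' @rdname replay_buffer
#' @param buf A replay buffer.
#' @param state,next_state Numeric vectors in `[0, 1]`.
#' @param action Integer action index.
#' @param reward Finite scalar reward.
#' @param terminal Logical flag.
#' @export
buffer_push <- function(buf, state, action, reward, next_state, terminal) {
  stopifnot(is.finite(reward), length(state) == buf$state_size)
  i <- buf$head %% buf$capacity + 1L
  # subassign inside the buffer environment: keeps the (large) storage
  # matrices un-shared so R updates them in place instead of copying
  assign("..i", i, envir = buf)
  assign("..s", as.raw(round(state * 255)), envir = buf)
  assign("..s2", as.raw(round(next_state * 255)), envir = buf)
  evalq({ s[, ..i] <- ..s; s2[, ..i] <- ..s2 }, buf)
  buf$a[i] <- as.integer(action)
  buf$r[i] <- reward
  buf$terminal[i] <- isTRUE(terminal)
  buf$head <- buf$head + 1L
  buf$size <- min(buf$size + 1L, buf$capacity)
  invisible(buf)
}

#' @rdname replay_buffer
#' @param n Batch size; sampling requires `buffer_size(buf) >= n`.
#' @export
buffer_sample <- function(buf, n) {
  if (buf$size < n) stop("not enough transitions stored to sample a batch")
  idx <- sample.int(buf$size, n, replace = FALSE)
  list(
    state = matrix(as.integer(buf$s[, idx]) / 255, buf$state_size, n),
    next_state = matrix(as.integer(buf$s2[, idx]) / 255, buf$state_size, n),
    action = buf$a[idx],
    reward = buf$r[idx],
    terminal = buf$terminal[idx]
  )
}

#' @rdname replay_buffer
#' @export
buffer_size <- function(buf) buf$size

#' Epsilon-greedy action selection
#'
#' With probability `epsilon` a uniform random action, otherwise the argmax
#' of the Q-values with lowest-index tie-break. Deterministic given the RNG
#' state.
#'
#' @param q Finite numeric vector of Q-values.
#' @param epsilon Exploration probability in `[0, 1]`.
#' @return Action index (1-based).
#' @export
select_action <- function(q, epsilon = 0) {
  if (length(q) == 0) stop("empty Q-value vector")
  if (anyNA(q) || any(!is.finite(q))) stop("Q-values must be finite")
  stopifnot(epsilon >= 0, epsilon <= 1)
  if (epsilon > 0 && runif(1) < epsilon) sample.int(length(q), 1L)
  else which.max(q)
}

#' Training configuration
#'
#' Hyperparameters of the DQN loop. The defaults follow DQN convention
#' (the settings that matter are all exposed): discount 0.99, replay capacity
#' 1e5, batch 32, target sync every 1000 steps, epsilon annealed linearly
#' 1.0 to 0.05 over 1e4 steps, Adam at 1e-4, updates every 4 environment
#' steps after a 500-transition warm-up, rewards clipped to `[-1, 1]`.
#'
#' @param T Simulation steps per network inference.
#' @param gamma Discount factor.
#' @param lr Adam learning rate.
#' @param batch_size Replay batch size.
#' @param buffer_capacity Replay capacity.
#' @param target_sync Steps between target-network synchronizations.
#' @param eps_start,eps_end,eps_decay_steps Linear epsilon schedule.
#' @param total_steps Environment steps to run.
#' @param train_every Environment steps per gradient update.
#' @param warmup Transitions stored before learning starts.
#' @param frame_stack Number of stacked past frames forming a state.
#' @param clip_rewards Clip rewards to `[-1, 1]`.
#' @param grad_clip Global-norm gradient clip (`Inf` = off).
#' @param diag_every Episodes between firing-rate diagnostic records
#'   (`0` disables).
#' @param seed Master seed; the run is reproducible given it.
#' @return Object of class `"train_config"`.
#' @export
train_config <- function(T = 16L, gamma = 0.99, lr = 1e-4, batch_size = 32L,
                         buffer_capacity = 1e5, target_sync = 1000L,
                         eps_start = 1.0, eps_end = 0.05,
                         eps_decay_steps = 1e4, total_steps = 2e4,
                         train_every = 4L, warmup = 500L,
                         frame_stack = 4L, clip_rewards = TRUE,
                         grad_clip = Inf, diag_every = 50L, seed = 1L) {
  stopifnot(T >= 1, gamma >= 0, gamma <= 1,
            eps_start >= 0, eps_start <= 1, eps_end >= 0, eps_end <= 1,
            batch_size >= 1, total_steps >= 0, frame_stack >= 1)
  structure(as.list(environment()), class = "train_config")
}

epsilon_at <- function(cfg, step) {
  frac <- min(1, step / cfg$eps_decay_steps)
  cfg$eps_start + frac * (cfg$eps_end - cfg$eps_start)
}

stack_to_state <- function(stack) {
  # stack: list of (H x W) frames, oldest first -> (C, H, W) channel-fastest
  arr <- array(0, dim = c(length(stack), dim(stack[[1]])))
  for (i in seq_along(stack)) arr[i, , ] <- stack[[i]]
  as.vector(arr)
}

#' Train a spiking deep Q-network
#'
#' The standard DQN loop around the spiking network: act epsilon-greedily,
#' store the transition, sample a replay batch, form the TD target with a
#' periodically synchronized frozen target network, backpropagate the
#' squared TD error through layers and time with the surrogate gradient, and
#' apply an Adam step. Fully reproducible given `config$seed` (single
#' threaded). If the loss turns non-finite the run aborts, returning the
#' last finite network state in the error condition.
#'
#' @param env A [catch_env()] (or any object honouring the same
#'   reset/step/`n_actions`/`obs_shape` contract).
#' @param config A [train_config()].
#' @param net Optional pre-built [sdqn_network()]; by default one is built
#'   for the environment's frame shape.
#' @param pbln Use pbLN during training (paired off-switch for ablations).
#' @param ... Arguments forwarded to [sdqn_network()] when `net` is `NULL`.
#' @return List of class `"sdqn_training"`: the trained `net`, the episode
#'   `log` (data frame: episode, steps, reward, epsilon, mean loss), a
#'   `diagnostics` data frame of periodic per-layer firing fractions, and
#'   the `config`.
#' @export
sdqn_train <- function(env, config = train_config(), net = NULL,
                       pbln = TRUE, ...) {
  set.seed(config$seed)
  obs <- env_reset(env, seed = config$seed + 1000L)
  if (is.null(net)) {
    net <- sdqn_network(input_shape = c(config$frame_stack, dim(obs)),
                        n_actions = env$n_actions, T = config$T, ...)
  }
  target <- net
  params <- net_params(net)
  opt <- adam_init(params)
  state_size <- prod(net$input_shape)
  buf <- replay_buffer(config$buffer_capacity, state_size)

  stack <- rep(list(obs), config$frame_stack)
  state <- stack_to_state(stack)
  log <- list()
  diag_log <- list()
  ep <- 1L; ep_reward <- 0; ep_steps <- 0L; ep_losses <- numeric(0)
  last_finite <- net

  step <- 0L
  while (step < config$total_steps) {
    step <- step + 1L
    eps <- epsilon_at(config, step)
    q <- network_forward(net, state, T = config$T, pbln = pbln)$q
    a <- select_action(q, eps)
    res <- env_step(env, a)
    r <- if (config$clip_rewards) max(-1, min(1, res$reward)) else res$reward
    stack <- c(stack[-1], list(res$observation))
    next_state <- stack_to_state(stack)
    buffer_push(buf, state, a, r, next_state, res$terminal)
    state <- next_state
    ep_reward <- ep_reward + res$reward
    ep_steps <- ep_steps + 1L

    if (buffer_size(buf) >= max(config$warmup, config$batch_size) &&
        step %% config$train_every == 0L) {
      batch <- buffer_sample(buf, config$batch_size)
      tq <- network_forward(target, batch$next_state, T = config$T, pbln = pbln)$q
      q_next_max <- Reduce(pmax, asplit(tq, 1))
      y <- batch$reward +
        config$gamma * q_next_max * (1 - batch$terminal)
      fwd <- network_forward(net, batch$state, T = config$T, pbln = pbln,
                             record = TRUE)
      B <- config$batch_size
      q_sa <- fwd$q[cbind(batch$action, seq_len(B))]
      dq <- matrix(0, net$n_actions, B)
      dq[cbind(batch$action, seq_len(B))] <- -2 * (y - q_sa) / B
      loss <- mean((y - q_sa)^2)
      if (!is.finite(loss)) {
        cond <- simpleError("training diverged: non-finite TD loss")
        cond$checkpoint <- last_finite
        stop(cond)
      }
      grads <- network_backward(net, fwd, dq)
      grads <- clip_global_norm(grads, config$grad_clip)
      upd <- adam_update(params, grads, opt, lr = config$lr)
      params <- upd$params; opt <- upd$state
      net <- net_set_params(net, params)
      last_finite <- net
      ep_losses <- c(ep_losses, loss)
    }

    if (step %% config$target_sync == 0L) target <- net

    if (res$terminal) {
      log[[ep]] <- data.frame(episode = ep, steps = ep_steps,
                              reward = ep_reward, epsilon = eps,
                              loss = if (length(ep_losses)) mean(ep_losses)
                                     else NA_real_)
      if (config$diag_every > 0 && ep %% config$diag_every == 0L) {
        fr <- layer_firing_fractions(net, state, T = config$T, pbln = pbln)
        diag_log[[length(diag_log) + 1L]] <-
          data.frame(episode = ep, layer = names(fr),
                     firing_fraction = unname(fr))
      }
      ep <- ep + 1L; ep_reward <- 0; ep_steps <- 0L; ep_losses <- numeric(0)
      obs <- env_reset(env)
      stack <- rep(list(obs), config$frame_stack)
      state <- stack_to_state(stack)
    }
  }

  structure(list(net = net, target_net = target,
                 log = if (length(log)) do.call(rbind, log)
                       else data.frame(episode = integer(), steps = integer(),
                                       reward = numeric(), epsilon = numeric(),
                                       loss = numeric()),
                 diagnostics = if (length(diag_log)) do.call(rbind, diag_log)
                               else data.frame(),
                 config = config, pbln = pbln),
            class = "sdqn_training")
}

#' Evaluate a policy
#'
#' Greedy rollouts (optional small exploration epsilon) of a trained network,
#' reporting the mean and standard deviation of the episode rewards. Ten
#' episodes is the conventional test protocol.
#'
#' @param net A trained [sdqn_network()], or `NULL` for the uniform-random
#'   policy.
#' @param env A [catch_env()].
#' @param n_episodes Number of evaluation episodes, `>= 1`.
#' @param epsilon Exploration probability during evaluation.
#' @param seed Seed controlling both the policy RNG and the episode stream.
#' @param pbln Use pbLN in the forward pass.
#' @param T Simulation window (defaults to the network's).
#' @param frame_stack Frames per state (must match training).
#' @return List: `mean`, `sd`, `rewards` (per-episode vector).
#' @export
evaluate_policy <- function(net, env, n_episodes = 10L, epsilon = 0,
                            seed = 1L, pbln = TRUE, T = NULL,
                            frame_stack = 4L) {
  stopifnot(n_episodes >= 1)
  set.seed(seed)
  obs <- env_reset(env, seed = seed + 2000L)
  if (!is.null(net) && is.null(T)) T <- net$T
  rewards <- numeric(n_episodes)
  for (i in seq_len(n_episodes)) {
    if (i > 1L) obs <- env_reset(env)
    stack <- rep(list(obs), frame_stack)
    total <- 0
    repeat {
      a <- if (is.null(net)) sample.int(env$n_actions, 1L)
           else {
             q <- network_forward(net, stack_to_state(stack), T = T,
                                  pbln = pbln)$q
             select_action(q, epsilon)
           }
      res <- env_step(env, a)
      stack <- c(stack[-1], list(res$observation))
      total <- total + res$reward
      if (res$terminal) break
    }
    rewards[i] <- total
  }
  list(mean = mean(rewards), sd = stats::sd(rewards), rewards = rewards)
}
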