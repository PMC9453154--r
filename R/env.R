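# Self-contained seeded pixel RL environment (catch) and fixture generators,
# so every other module is testable without external assets.

# Run `expr` under the environment's private RNG stream, so episode
# randomness is reproducible independently of the global RNG state.
with_env_rng <- function(env, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  if (!is.null(env$rng_state)) assign(".Random.seed", env$rng_state, globalenv())
  on.exit({
    env$rng_state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, globalenv())
  })
  expr
}

#' Catch: a seeded pixel reinforcement-learning environment
#'
#' A ball drops from the top row of a square grid in a uniformly random
#' column; a paddle on the bottom row moves one cell per step (left / stay /
#' right, clamped at the walls). The episode ends when the ball reaches the
#' bottom row: reward `+1` if the ball column lies within the paddle span,
#' `-1` otherwise, `0` on every intermediate step. The logical grid is
#' rendered to a grayscale frame by nearest-neighbor upsampling (binary
#' sprites, pixel values in `{0, 1}`). The environment is fully solvable: a
#' greedy column-matching policy always catches.
#'
#' @param grid Logical grid side length (odd recommended so the paddle can
#'   start centered).
#' @param paddle_width Odd paddle width, `< grid`.
#' @param render_size Rendered frame side in pixels; must be a multiple of
#'   `grid` (84 gives the DQN-style 84x84 frame, 21 the native grid).
#' @param seed Seed of the environment's private RNG stream.
#' @return An environment object of class `"catch_env"` with fields
#'   `n_actions` (3) and `obs_shape`; drive it with [env_reset()] and
#'   [env_step()].
#' @export
catch_env <- function(grid = 21L, paddle_width = 3L, render_size = 84L,
                      seed = NULL) {
  stopifnot(paddle_width < grid, paddle_width %% 2 == 1,
            render_size %% grid == 0)
  e <- new.env(parent = emptyenv())
  e$grid <- as.integer(grid)
  e$paddle_width <- as.integer(paddle_width)
  e$half <- (as.integer(paddle_width) - 1L) %/% 2L
  e$scale <- as.integer(render_size) %/% as.integer(grid)
  e$n_actions <- 3L                    # 1 = left, 2 = stay, 3 = right
  e$obs_shape <- c(render_size, render_size)
  e$max_episode_steps <- as.integer(grid) - 1L
  e$done <- TRUE
  e$rng_state <- NULL
  if (!is.null(seed)) with_env_rng(e, set.seed(seed))
  class(e) <- "catch_env"
  e
}

render_catch <- function(env) {
  g <- env$grid
  m <- matrix(0, g, g)
  m[env$ball_row, env$ball_col] <- 1
  span <- max(1L, env$paddle_col - env$half):min(g, env$paddle_col + env$half)
  m[g, span] <- 1
  f <- env$scale
  if (f > 1L) m <- m[rep(seq_len(g), each = f), rep(seq_len(g), each = f)]
  m
}

#' Reset the environment to a new episode
#'
#' The ball appears at the top row in a seeded-random column and the paddle
#' starts centered. Re-seeding reproduces the episode sequence exactly.
#'
#' @param env A [catch_env()].
#' @param seed Optional reseed of the environment's private RNG stream.
#' @return The rendered initial observation (matrix in `[0, 1]`).
#' @export
env_reset <- function(env, seed = NULL) {
  stopifnot(inherits(env, "catch_env"))
  if (!is.null(seed)) with_env_rng(env, set.seed(seed))
  env$ball_row <- 1L
  env$ball_col <- with_env_rng(env, sample.int(env$grid, 1L))
  env$paddle_col <- (env$grid + 1L) %/% 2L
  env$steps <- 0L
  env$done <- FALSE
  render_catch(env)
}

#' Advance the environment one step
#'
#' @param env A [catch_env()] with an active episode.
#' @param action 1 (left), 2 (stay) or 3 (right).
#' @return List of class `"step_result"`: `observation` (rendered frame),
#'   `reward`, `terminal`, and an `info` list with the logical state.
#' @export
env_step <- function(env, action) {
  stopifnot(inherits(env, "catch_env"))
  if (env$done) stop("episode is over; call env_reset() first")
  if (!action %in% 1:3) stop("action must be 1 (left), 2 (stay) or 3 (right)")
  dx <- c(-1L, 0L, 1L)[action]
  env$paddle_col <- min(max(env$paddle_col + dx, 1L + env$half),
                        env$grid - env$half)
  env$ball_row <- env$ball_row + 1L
  env$steps <- env$steps + 1L
  reward <- 0
  if (env$ball_row >= env$grid) {
    env$done <- TRUE
    caught <- abs(env$ball_col - env$paddle_col) <= env$half
    reward <- if (caught) 1 else -1
  }
  structure(list(observation = render_catch(env), reward = reward,
                 terminal = env$done,
                 info = list(ball_row = env$ball_row, ball_col = env$ball_col,
                             paddle_col = env$paddle_col, steps = env$steps)),
            class = "step_result")
}

#' Greedy column-matching policy for catch
#'
#' Moves the paddle one cell toward the ball column; achieves reward 1 on
#' every episode (the environment's known performance ceiling).
#'
#' @param env A [catch_env()] with an active episode.
#' @return The optimal action (1, 2 or 3).
#' @export
optimal_catch_action <- function(env) {
  if (env$ball_col < env$paddle_col) 1L
  else if (env$ball_col > env$paddle_col) 3L
  else 2L
}

#' Exact expected reward of the uniform-random policy on catch
#'
#' Computed by dynamic programming: for each drop column, the paddle-center
#' distribution under uniform random actions (a clamped random walk) is
#' evolved for the episode length, and the catch probability is the final
#' mass within the paddle span. No simulation involved; serves as the
#' analytic oracle for evaluation routines.
#'
#' @param grid,paddle_width As in [catch_env()].
#' @return Expected terminal reward (`2 * P(catch) - 1` averaged over drop
#'   columns).
#' @export
catch_random_policy_value <- function(grid = 21L, paddle_width = 3L) {
  half <- (paddle_width - 1L) %/% 2L
  lo <- 1L + half
  hi <- grid - half
  n_steps <- grid - 1L
  p <- numeric(grid)
  p[(grid + 1L) %/% 2L] <- 1
  for (s in seq_len(n_steps)) {
    q <- numeric(grid)
    for (c in lo:hi) {
      if (p[c] == 0) next
      left <- max(c - 1L, lo); right <- min(c + 1L, hi)
      q[left] <- q[left] + p[c] / 3
      q[c] <- q[c] + p[c] / 3
      q[right] <- q[right] + p[c] / 3
    }
    p <- q
  }
  catch_prob <- vapply(seq_len(grid), function(ball) {
    span <- max(lo, ball - half):min(hi, ball + half)
    sum(p[span][abs(span - ball) <= half])
  }, numeric(1))
  mean(2 * catch_prob - 1)
}

#' Bernoulli spike-train fixtures
#'
#' I.i.d. Bernoulli spikes matching the requested per-step means — the
#' controlled presynaptic input of the variance-propagation oracle.
#'
#' @param n_neurons Number of neurons.
#' @param T Time steps.
#' @param means Per-step spike probability (scalar or length-`T` vector),
#'   each in `[0, 1]`.
#' @param seed Optional seed.
#' @return A `(T x n_neurons)` [spike_train()].
#' @export
make_spike_fixtures <- function(n_neurons, T, means = 0.3, seed = NULL) {
  stopifnot(n_neurons >= 1, T >= 1)
  if (any(means < 0 | means > 1)) stop("spike means must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  means <- rep_len(means, T)
  o <- matrix(rbinom(T * n_neurons, 1L, rep(means, n_neurons)), T, n_neurons)
  spike_train(o)
}

#' Synthetic input frames for diagnostics
#'
#' Stand-ins for preprocessed game frames: `"uniform"` draws dense
#' uniform-[0,1] pixels (natural-image-like energy), `"sparse"` scatters a
#' few bright pixels on black (catch-like sprite statistics), `"catch"`
#' renders an actual environment observation stack.
#'
#' @param shape `c(channels, H, W)`.
#' @param source Frame statistics to emulate.
#' @param density Fraction of bright pixels for `"sparse"`.
#' @return Array `(channels, H, W)` with values in `[0, 1]`.
#' @export
random_frames <- function(shape = c(4, 84, 84),
                          source = c("uniform", "sparse", "catch"),
                          density = 0.02) {
  source <- match.arg(source)
  n <- prod(shape)
  x <- switch(source,
    uniform = runif(n),
    sparse = (runif(n) < density) + 0,
    catch = {
      env <- catch_env(render_size = shape[2],
                       seed = sample.int(.Machine$integer.max, 1L))
      obs <- env_reset(env)
      frames <- array(0, dim = shape)
      for (ch in seq_len(shape[1])) {
        frames[ch, , ] <- obs
        if (!env$done) obs <- env_step(env, sample.int(3L, 1L))$observation
      }
      return(frames)
    })
  array(x, dim = shape)
}
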