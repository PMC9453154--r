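#' LIF neuron parameters
#'
#' Bundles the constants of the discrete-time leaky integrate-and-fire neuron:
#' the membrane time constant `tau` (in simulation steps), the firing threshold
#' `v_th`, the reset potential `v_reset`, and the derived per-step decay factor
#' `alpha = 1 - 1/tau`. The membrane update is
#' `u[t+1] = alpha * u[t] + (1 - alpha) * x[t]`, a spike is emitted when the
#' updated potential reaches `v_th`, and the potential is then hard-reset to
#' `v_reset`.
#'
#' `alpha` is always recomputed from `tau`, never stored independently.
#'
#' @param tau Membrane time constant in steps, `>= 1`. `tau = 1` is the
#'   memoryless limit (`alpha = 0`).
#' @param v_th Firing threshold potential; must exceed `v_reset`.
#' @param v_reset Reset potential, also the initial potential at `t = 0`.
#' @return An object of class `"lif_params"`.
#' @examples
#' p <- lif_params(tau = 2)     # alpha = 0.5
#' p$alpha
#' @export
lif_params <- function(tau = 2, v_th = 0.5, v_reset = 0) {
  stopifnot(is.numeric(tau), length(tau) == 1L,
            is.numeric(v_th), length(v_th) == 1L,
            is.numeric(v_reset), length(v_reset) == 1L)
  if (!is.finite(tau) || tau < 1)
    stop("`tau` must be finite and >= 1 (tau < 1 would make the decay factor negative)")
  if (v_th <= v_reset)
    stop("`v_th` must be strictly greater than `v_reset`")
  structure(
    list(tau = tau, v_th = v_th, v_reset = v_reset, alpha = decay_factor(tau)),
    class = "lif_params"
  )
}

#' @export
print.lif_params <- function(x, ...) {
  cat(sprintf("LIF parameters: tau = %g (alpha = %g), v_th = %g, v_reset = %g\n",
              x$tau, x$alpha, x$v_th, x$v_reset))
  invisible(x)
}

#' Membrane decay factor
#'
#' `alpha = 1 - 1/tau`, the fraction of membrane potential retained per step.
#'
#' @param tau Membrane time constant, `>= 1`.
#' @return The decay factor in `[0, 1)`.
#' @examples
#' decay_factor(2)  # 0.5
#' decay_factor(1)  # 0, memoryless
#' @export
decay_factor <- function(tau) {
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) || tau < 1)
    stop("`tau` must be a finite numeric scalar >= 1")
  1 - 1 / tau
}

#' Heaviside step function with firing boundary at zero
#'
#' Returns 1 where `v >= 0` and 0 elsewhere. The boundary convention is that
#' equality fires: the threshold-crossing event `u - v_th = 0` is a zero-measure
#' case and resolving it deterministically to a spike keeps the dynamics
#' testable.
#'
#' @param v Numeric vector/array of potential offsets (typically `u - v_th`).
#' @return Numeric array of 0/1 with the shape of `v`.
#' @examples
#' heaviside(c(-0.1, 0, 0.3))  # 0 1 1
#' @export
heaviside <- function(v) {
  if (!is.numeric(v)) stop("`v` must be numeric")
  if (anyNA(v) || any(!is.finite(v)))
    stop("`heaviside()` received non-finite input; refusing to silently return 0")
  out <- (v >= 0) + 0
  attributes(out) <- attributes(v)
  out
}

#' Create a neuron state
#'
#' Membrane potentials start at `v_reset` at `t = 0`; every forward inference
#' re-initializes its state (no carry-over across environment steps).
#'
#' @param n Number of neurons.
#' @param params A [lif_params()] object.
#' @return An object of class `"neuron_state"` with fields `u` (potentials)
#'   and `t` (step counter).
#' @export
neuron_state <- function(n, params = lif_params()) {
  stopifnot(inherits(params, "lif_params"), n >= 1)
  structure(list(u = rep(params$v_reset, n), t = 0L), class = "neuron_state")
}

#' One leaky integrate-and-fire step
#'
#' Applies the membrane update `u' = alpha * u + (1 - alpha) * psp`, emits
#' spikes `H(u' - v_th)`, and hard-resets spiking neurons to `v_reset`.
#'
#' @param state A [neuron_state()].
#' @param psp Numeric vector of input drive (post-synaptic potential), one
#'   value per neuron.
#' @param params A [lif_params()] object.
#' @return A list with `state` (updated [neuron_state()], `t` incremented),
#'   `spikes` (0/1 vector), and `u_pre` (the pre-reset potential, needed by
#'   the surrogate-gradient backward pass).
#' @examples
#' p <- lif_params(tau = 2, v_th = 0.5, v_reset = 0)
#' s <- neuron_state(1, p); s$u <- 0.4
#' lif_step(s, psp = 1.0, p)  # u' = 0.7 >= 0.5 -> spike, reset to 0
#' @export
lif_step <- function(state, psp, params) {
  stopifnot(inherits(state, "neuron_state"), inherits(params, "lif_params"))
  if (!is.numeric(psp)) stop("`psp` must be numeric")
  if (length(psp) != length(state$u))
    stop(sprintf("shape mismatch: %d psp values for %d neurons",
                 length(psp), length(state$u)))
  if (anyNA(psp) || any(!is.finite(psp))) stop("`psp` contains non-finite values")
  u_pre <- params$alpha * state$u + (1 - params$alpha) * psp
  spikes <- heaviside(u_pre - params$v_th)
  u_new <- u_pre * (1 - spikes) + params$v_reset * spikes
  list(
    state = structure(list(u = u_new, t = state$t + 1L), class = "neuron_state"),
    spikes = spikes,
    u_pre = u_pre
  )
}

#' Binary spike train
#'
#' A `(time step x neuron)` matrix of 0/1 spikes. Binarity gives the moment
#' identity `mean(o^2) == mean(o)` used throughout the variance analysis.
#'
#' @param o Matrix (or vector, treated as one neuron) of 0/1 values.
#' @return The matrix with class `"spike_train"`.
#' @export
spike_train <- function(o) {
  if (is.vector(o)) o <- matrix(o, ncol = 1L)
  if (!is.matrix(o)) stop("`o` must be a matrix (time x neuron)")
  if (anyNA(o) || !all(o == 0 | o == 1))
    stop("spike train entries must be exactly 0 or 1")
  structure(o, class = c("spike_train", class(matrix())))
}

#' @rdname spike_train
#' @param x A spike train.
#' @export
n_steps <- function(x) nrow(x)

#' Run an LIF neuron array over a PSP sequence
#'
#' Applies [lif_step()] sequentially over the rows of `psp_sequence` and
#' records the emitted spikes and the *post-reset* potential at every step.
#'
#' @param psp_sequence Matrix `(time x neuron)` of input drive.
#' @param params A [lif_params()] object.
#' @param initial Optional [neuron_state()]; defaults to rest at `v_reset`.
#' @return List with `spikes` (a [spike_train()]), `potential` (post-reset
#'   trace, `time x neuron`), and `u_pre` (pre-reset trace).
#' @examples
#' p <- lif_params()
#' tr <- run_trace(matrix(0, 8, 3), p)
#' all(tr$spikes == 0)
#' @export
run_trace <- function(psp_sequence, params, initial = NULL) {
  if (is.vector(psp_sequence)) psp_sequence <- matrix(psp_sequence, ncol = 1L)
  stopifnot(is.matrix(psp_sequence), nrow(psp_sequence) >= 1)
  n <- ncol(psp_sequence)
  state <- if (is.null(initial)) neuron_state(n, params) else initial
  T_len <- nrow(psp_sequence)
  o <- matrix(0, T_len, n)
  u <- matrix(0, T_len, n)
  u_pre <- matrix(0, T_len, n)
  for (t in seq_len(T_len)) {
    st <- lif_step(state, psp_sequence[t, ], params)
    state <- st$state
    o[t, ] <- st$spikes
    u[t, ] <- state$u
    u_pre[t, ] <- st$u_pre
  }
  list(spikes = spike_train(o), potential = u, u_pre = u_pre)
}

#' Export a potential/spike trace as a tidy table
#'
#' @param trace The result of [run_trace()].
#' @return A data frame with columns `step`, `neuron_id`, `potential`, `spike`.
#' @export
trace_table <- function(trace) {
  T_len <- nrow(trace$potential)
  n <- ncol(trace$potential)
  data.frame(
    step = rep(seq_len(T_len), times = n),
    neuron_id = rep(seq_len(n), each = T_len),
    potential = as.vector(trace$potential),
    spike = as.vector(unclass(trace$spikes))
  )
}
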