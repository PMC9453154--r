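# Layer-wise spiking-activity statistics and membrane-potential trace
# capture: the instrumentation behind the spike-vanishing evidence.

#' Fraction of neurons with any firing activity
#'
#' The ratio of neurons emitting at least one spike within the simulation
#' window to the layer's total neuron count. Depends on the train only
#' through the per-neuron any-spike indicator, so it is invariant to
#' permuting spike times.
#'
#' @param spike_train A [spike_train()] `(T x n)`.
#' @return Fraction in `[0, 1]`.
#' @examples
#' firing_fraction(spike_train(rbind(c(1, 0, 0), c(1, 0, 0))))  # 1/3
#' @export
firing_fraction <- function(spike_train) {
  o <- unclass(spike_train)
  if (length(o) == 0) stop("empty spike train")
  mean(colSums(o) > 0)
}

#' Mean spikes per neuron over the window
#'
#' @param spike_train A [spike_train()].
#' @return Mean spike count per neuron.
#' @export
mean_spike_count <- function(spike_train) {
  o <- unclass(spike_train)
  sum(o) / ncol(o)
}

# Firing fractions per spiking layer from one recorded single-sample forward.
layer_firing_fractions <- function(net, input, T = net$T, pbln = TRUE) {
  fwd <- network_forward(net, input, T = T, pbln = pbln, record = TRUE)
  vapply(fwd$spike_trains, firing_fraction, numeric(1))
}

#' Layer-wise firing profile with and without pbLN
#'
#' The spike-vanishing experiment: a randomly initialized network is run on
#' freshly drawn input frames, and each layer's firing fraction (plus the
#' mean spike count per neuron) is recorded. Paired-seed discipline: the
#' pbLN-on and pbLN-off passes share the same weights and the same frames in
#' every run, so any difference is attributable to the normalization alone.
#'
#' @param net An [sdqn_network()] carrying pbLN states; if `NULL`, a fresh
#'   default-architecture network is drawn per `seed`.
#' @param n_runs Forward passes on fresh inputs (10 is the conventional
#'   protocol).
#' @param seed Seed for weights and frames.
#' @param pbln `"both"` (paired), `"on"`, or `"off"`.
#' @param frame_source Passed to [random_frames()].
#' @param T Simulation window.
#' @return Data frame of class `"firing_report"` with columns `layer`,
#'   `pbln`, `run`, `firing_fraction`, `mean_spike_count`; per-layer
#'   mean/SD summary in `attr(, "summary")`.
#' @export
depth_profile <- function(net = NULL, n_runs = 10L, seed = 1L,
                          pbln = c("both", "on", "off"),
                          frame_source = "uniform", T = NULL) {
  pbln <- match.arg(pbln)
  set.seed(seed)
  if (is.null(net)) net <- sdqn_network(n_actions = 10L)
  if (is.null(T)) T <- net$T
  settings <- switch(pbln, both = c(TRUE, FALSE), on = TRUE, off = FALSE)
  rows <- list()
  for (run in seq_len(n_runs)) {
    frames <- random_frames(net$input_shape, source = frame_source)
    for (use in settings) {
      fwd <- network_forward(net, frames, T = T, pbln = use, record = TRUE)
      for (nm in names(fwd$spike_trains)) {
        st <- fwd$spike_trains[[nm]]
        rows[[length(rows) + 1L]] <- data.frame(
          layer = nm, pbln = use, run = run,
          firing_fraction = firing_fraction(st),
          mean_spike_count = mean_spike_count(st))
      }
    }
  }
  out <- do.call(rbind, rows)
  agg <- stats::aggregate(cbind(firing_fraction, mean_spike_count) ~ layer + pbln,
                          data = out, FUN = mean)
  sds <- stats::aggregate(firing_fraction ~ layer + pbln, data = out,
                          FUN = stats::sd)
  names(sds)[3] <- "firing_fraction_sd"
  attr(out, "summary") <- merge(agg, sds, by = c("layer", "pbln"))
  attr(out, "n_runs") <- n_runs
  class(out) <- c("firing_report", class(out))
  out
}

#' Membrane-potential maintenance under pbLN
#'
#' Drives a small population with a pulse schedule separated by long gaps
#' (at least `3 * tau` steps) and records the tracked neuron's potential
#' with pbLN off (raw LIF: geometric decay toward `v_reset` at factor
#' `alpha` per step) and with pbLN on, where the affine shift `beta` acts as
#' a learned baseline the potential decays toward instead. At
#' initialization `beta = v_reset`, so the two asymptotes coincide; the
#' default `pbln` state uses a representative trained baseline
#' `beta = 0.5 * v_th` to exhibit the maintained-potential effect.
#'
#' @param pulse_times Steps at which the tracked neuron receives a
#'   supra-threshold raw PSP pulse.
#' @param T_total Trace length in steps.
#' @param pulse_height Raw PSP amplitude of each pulse.
#' @param params A [lif_params()].
#' @param pbln A [pbln_state()] for the on-trace; defaults to the
#'   representative trained state described above.
#' @param n_neighbors Population size over which pbLN normalizes; neighbors
#'   receive i.i.d. Gaussian background PSP.
#' @param noise_sd Background PSP standard deviation.
#' @param seed Seed for the background noise.
#' @return Data frame with matching time indices: `step`, `pulse`,
#'   `potential_off`, `spike_off`, `potential_on`, `spike_on`.
#' @export
potential_trace_report <- function(pulse_times = c(3L, 15L),
                                   T_total = 24L, pulse_height = 2,
                                   params = lif_params(),
                                   pbln = NULL, n_neighbors = 64L,
                                   noise_sd = 0.3, seed = 1L) {
  if (length(pulse_times) > 1 && min(diff(sort(pulse_times))) < 3 * params$tau)
    stop("pulse schedule must leave gaps of at least 3 * tau steps")
  if (is.null(pbln)) {
    pbln <- pbln_state(n_neighbors, params)
    pbln$beta <- rep(0.5 * params$v_th, n_neighbors)
  }
  set.seed(seed)
  raw <- matrix(rnorm(T_total * n_neighbors, 0, noise_sd), T_total, n_neighbors)
  raw[, 1] <- 0
  raw[pulse_times, 1] <- pulse_height
  off <- run_trace(raw, params)
  state <- neuron_state(n_neighbors, params)
  pot_on <- numeric(T_total); sp_on <- numeric(T_total)
  for (t in seq_len(T_total)) {
    st <- pbln_lif_step(state, raw[t, ], pbln, params)
    state <- st$state
    pot_on[t] <- state$u[1]
    sp_on[t] <- st$spikes[1]
  }
  data.frame(step = seq_len(T_total),
             pulse = as.integer(seq_len(T_total) %in% pulse_times),
             potential_off = off$potential[, 1],
             spike_off = unclass(off$spikes)[, 1],
             potential_on = pot_on,
             spike_on = sp_on)
}
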