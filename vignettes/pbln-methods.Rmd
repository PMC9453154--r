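---
title: "Potential-based layer normalization in spiking deep Q-networks: models, theory, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Potential-based layer normalization in spiking deep Q-networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdqn)
```

## The neuron and network model

Every spiking layer in this package is built on the discrete-time leaky
integrate-and-fire (LIF) neuron. With decay factor $\alpha = 1 - 1/\tau$,
membrane potential $u$, and input drive (post-synaptic potential, PSP) $x$:

$$u_{t+1} = \alpha\, u_t + (1-\alpha)\, x_t, \qquad
  o_{t+1} = H(u_{t+1} - V_{th}), \qquad
  u \leftarrow V_{reset} \text{ where } o = 1 .$$

`heaviside()` resolves the zero-measure boundary case deterministically:
equality fires, $H(0) = 1$. The reset is a hard reset to `v_reset`, not a
subtraction. Membrane state is re-initialized at `v_reset` at the start of
every forward inference — each action selection runs a fresh $T$-step
simulation, which matches the time-window readout below; no carry-over
across environment steps is assumed.

The PSP of a convolutional layer is a valid (unpadded) cross-correlation of
the previous layer's binary spike map with the kernels; a fully-connected
layer's PSP is the weighted sum of presynaptic spikes. Input pixels are
injected as a *constant real-valued current*: the same frame array drives
the first conv layer at every one of the $T$ steps (no Poisson encoding).
Q-values are read out by a non-spiking linear head averaging the hidden
spike train over the window:

$$q_i = \frac{1}{T}\sum_{t=0}^{T-1} W_i \cdot O_t .$$

The default architecture is the DQN stack `c32k8-c64k4-c64k3` with strides
4, 2, 1 on a 4×84×84 grayscale frame stack, 512 hidden neurons, and an
environment-driven number of actions. Strides are not part of the
architecture string and default to the canonical DQN values.

Default neuron constants, exposed in every configuration and never
hard-coded in operations: $\tau = 2$ steps ($\alpha = 0.5$),
$V_{th} = 0.5$, $V_{reset} = 0$. They are dimensionless simulation units;
only the ratio of drive to threshold matters.

## Why spike features vanish with depth

For a layer whose weights are drawn i.i.d. with mean zero and variance
$D(W)$, independently of the presynaptic activity, the sub-threshold
potential after integrating presynaptic steps $0..t$ has variance

$$D(u_{t+1}) \;=\; D(W) \sum_{i=0}^{t} \psi(i,t)\, E[o_i^{\,l-1}],
  \qquad \psi(i,j) = (1-\alpha)^2 \alpha^{2(j-i)} \in (0,1],$$

per synapse; contributions add over `n_pre` independent presynaptic
neurons (`predicted_potential_variance()`, with `n_pre = 1` the literal
per-synapse form). Because spikes are binary, $E[o^2] = E[o]$, which is why
the *first* moment of the presynaptic activity appears in a variance
formula. Defining the signal-loss ratio

$$\varepsilon = \frac{D(W)}{2 V_{th}^2},$$

the spike probability of a neuron that has integrated $t$ presynaptic
steps is bounded by $\varepsilon$ times the presynaptic spike mass it
received (`spike_mean_bound()`). When $\varepsilon < 1$ — for the standard
scaled-uniform initialization $D(W) = 1/(3\,\mathrm{fan_{in}})$ it is far
below 1 — iterating the bound across layers shrinks the admissible spike
mass geometrically: deep layers of a randomly initialized spiking network
go silent. `depth_profile()` exhibits exactly this on the full
architecture: conv1 retains a few percent of active neurons, conv2 and
conv3 essentially none.

Two points about how the Monte-Carlo oracle (`monte_carlo_layer()`) is set
up deserve emphasis, because they are where a naive simulation diverges
from the formula:

* **What is simulated.** The variance formula describes sub-threshold
  accumulation — the potential of a neuron *before its first spike*. The
  oracle therefore records the unconditional no-reset accumulation, which
  is that process realized exactly. Conditioning the ensemble on
  "no spike before $t$" (i.e. discarding trials) truncates the upper tail
  and biases the variance estimator downward; the oracle instead reports
  the cumulative first-passage rate as a diagnostic column
  (`exclusion_rate`) without applying it.
* **Independence of the weight draw.** The derivation treats each step's
  weighted input as independent of the accumulated history. With one
  weight draw held fixed across the window, cross-step covariance terms
  $D(W)\,c_i c_j E(o_i)E(o_j)$ appear that the formula omits — at spike
  mean 0.5 and $\alpha = 0.75$ they exceed the predicted variance itself.
  The oracle therefore resamples weights at every step by default, which
  realizes the independence premise; `resample_weights = FALSE` is kept
  precisely to demonstrate the omitted terms (a unit test asserts the
  deviation).

The variance sum indexes presynaptic steps from 0 while the bound's sum
starts at $i = 1$; these are two numbering origins for the same quantity
(all integrated input steps), not a dropped term. Reading the bound as
literally excluding the first input would make it zero for a neuron that
can already fire after one input, i.e. trivially false; `spike_mean_bound()`
implements the coherent reading and documents it.

## Potential-based layer normalization

pbLN standardizes the *PSP* (not the spikes) of a conv layer at each time
step over all of its $H = C \times H \times W$ elements jointly:

$$\hat{x}_t = \frac{x_t - \bar{x}_t}{\sigma_{x_t} + \epsilon}, \qquad
  u_{t+1} = \alpha u_t + (1-\alpha)\,[\lambda \hat{x}_t + \beta],$$

with *population* variance (divide by $H$), the stability constant
$\epsilon = 10^{-5}$ added to the standard deviation, and a learnable
per-channel scale/shift initialized at

$$\lambda_0 = V_{th} - V_{reset}, \qquad \beta_0 = V_{reset}.$$

This initialization has a useful calibration: a $+1$-standard-deviation
normalized input produces pre-leak drive exactly $V_{th}$, so roughly the
upper one-sigma tail of each layer's PSP distribution can reach threshold
regardless of how small the raw weight-driven variance has become. That is
the rescue mechanism: $\lambda$ plays the role of a large effective
$D(W)$ without destabilizing training, and $\beta$ acts as a learnable
dynamic baseline/threshold offset.

Statistics are computed independently at each time step on the single
sample being processed — deliberately *not* batched and *not* aggregated
over time, because the reinforcement-learning data stream is unbatched and
future PSPs are unavailable during online inference. Normalization is
applied in conv layers by default; `pbln_fc = TRUE` extends it to hidden
FC layers for ablations.

Where the scale/shift carries a time subscript, the package shares one
$(\lambda, \beta)$ pair per channel across the window by default (a single
initialization pair is all the theory specifies); `pbln_per_step = TRUE`
switches to separate parameters per simulation step for fidelity
experiments. Both variants are exercised by the gradient tests.

## Learning

Training minimizes the squared TD error
$L = E[(r + \gamma \max_{a'} Q(s',a') - Q(s,a))^2]$ with a frozen,
periodically synchronized target network, experience replay, an
$\varepsilon$-greedy behaviour policy, and Adam. The TD error itself is
the half-scaled $\delta = \tfrac12(r + \gamma \max Q' - Q)$ convention
(`td_error()`).

Backpropagation runs through both depth and time. At the spike
discontinuity the derivative $\partial o/\partial u$ is replaced by the
normalized bump

$$g(v) = \frac{2\tau_s}{4 + (\pi \tau_s v)^2}, \qquad
  v = u - V_{th},$$

with $\tau_s = 2$ by default. Three choices here are deliberate:

* **Centering.** The bump is evaluated at $u - V_{th}$ so its peak sits at
  the firing discontinuity, which is its role as a surrogate of
  $\partial H(u - V_{th})/\partial u$; the literal uncentered form (peak
  at $u = 0$) is preserved behind `centered_surrogate = FALSE`.
* **Sharpness constant.** $\tau_s$ is independent of the membrane $\tau$;
  the two constants play unrelated roles and are configured separately.
* **Detached reset.** Gradients do not flow through the reset assignment
  in the discrete model; the recurrence contributes a factor $\alpha$ on
  non-spiking steps. The backward recursion runs over the full horizon
  (the printed index bounds of the temporal chain are typographically
  ambiguous; the standard full-horizon BPTT recursion is used).

pbLN's $\lambda, \beta$ gradients flow through the normalization
statistics, with mean and standard deviation treated as differentiable
functions of the PSP, exactly as in ordinary layer-norm training.

**Gradient verification.** The spiking forward is discontinuous, so
finite differences cannot check it directly. The package therefore also
implements the *surrogate-relaxed* network: the Heaviside spike is
replaced by the surrogate's antiderivative
$(1/\pi)\arctan(\pi\tau_s v/2) + 1/2$, making the whole forward smooth; in
this mode the backward pass additionally differentiates the reset gate.
Central finite differences of the relaxed network then verify the entire
backward machinery — temporal recursion, conv/FC weight paths, pbLN
statistics — to $10^{-4}$ relative error on 100 random small networks
(machine precision in practice). The discrete training path differs from
the verified path only in the hard spike and the detached reset, both
deliberate modeling choices rather than computational steps a finite
difference could confirm.

## The synthetic environment, and what passing tests show

`catch_env()` is a seeded pixel game: a ball drops from a uniformly random
column of a 21×21 grid; a 3-cell paddle moves one cell per step; terminal
reward ±1. It was chosen over classic control tasks because it exercises
the full convolutional pixel pipeline, like the video-game setting the
model targets, while remaining solvable in minutes on one CPU. Rendering
upsamples logical cells by nearest-neighbour blocks (84×84 by default, or
the native 21×21), so the standard preprocessing path is exercised
unchanged. The environment is fully solvable (`optimal_catch_action()`
always catches), and the uniform-random policy's expected reward has an
exact dynamic-programming value (`catch_random_policy_value()`) used as an
analytic oracle — $-5/7 \approx -0.714$ for the default geometry.

What catch does *not* emulate: the visual complexity, reward sparsity
variation, and long-horizon credit assignment of real game suites. A
passing training test shows that the spiking network, surrogate BPTT and
pbLN interact correctly as a learning system and that normalization
rescues learning when raw spiking activity is too sparse to carry a
gradient signal; it does not certify performance on full-scale games,
which requires GPU-scale training far outside this package's scope.

## Problem sizes

Simulation sizes were fixed once, as the package's CPU-scale study
conditions:

* **Theory grid:** $\alpha \in \{0.25, 0.5, 0.75\}$,
  $D(W) \in \{0.1, 0.5, 1.0\}$, spike mean $\in \{0.1, 0.3, 0.5\}$,
  $10^5$ trials, 10 presynaptic neurons, steps 1–8. At $10^5$ trials the
  Monte-Carlo standard error of a variance is ≈ 0.5% of its value, so the
  2% agreement margin is a real test, not noise absorption.
* **Firing diagnostics:** the full `c32k8-c64k4-c64k3` network, 10 paired
  runs on fresh dense uniform frames (dense frames carry natural-image-like
  energy into conv1; sparse sprite statistics are available via
  `frame_source = "sparse"`).
* **Training demonstration:** catch at its native 21×21 rendering with a
  2-frame stack, a `c8k5s2-c16k3s2` stack with 64 hidden neurons,
  $T = 4$, batch 16, Adam at $10^{-3}$, $2 \times 10^4$ environment steps
  (`smoke_run_config()`). The window $T = 4$ is the documented reduced
  setting for the training demonstration — readout averaging needs only
  enough steps to resolve a few spike counts on this small task — while
  $T = 16$ remains the package default for the full architecture. The
  learning rate reflects the small network and short run; the full-scale
  default stays at the conventional $10^{-4}$.

## Other numerical choices

* Degenerate pbLN input (constant PSP map): standard deviation is zero,
  the normalized output is defined as all-zero, and the condition is
  flagged; the backward pass guards the $1/\sigma$ term with a floor of
  $10^{-12}$ (random continuous PSPs never hit it).
* Greedy action ties break to the lowest index, making policies
  deterministic given Q-values.
* Replay frames are stored 8-bit quantized (0–255), the standard DQN
  memory layout; catch frames are binary so the round trip is lossless.
* Rewards are clipped to $[-1, 1]$ by default (toggleable); catch rewards
  are already in range.
* Everything is single-threaded and seeded: training runs are bitwise
  reproducible under a fixed configuration seed, and the environment keeps
  a private RNG stream so episode randomness is independent of the global
  RNG state.

## Known limitations

* The conv/BPTT engine is optimized for the package's problem sizes
  (im2col gathers plus BLAS products); it is not a general deep-learning
  runtime and has no GPU path.
* The variance theory addresses randomly initialized, zero-mean-weight
  layers; after training the weight distribution shifts and the formulas
  describe initialization-time behaviour only.
* pbLN couples neurons within a layer through the shared statistics, so
  single-neuron reasoning about thresholds no longer holds exactly — the
  potential-maintenance trace (`potential_trace_report()`) illustrates
  this, using a representative trained baseline $\beta = 0.5 V_{th}$
  because at initialization $\beta = V_{reset}$ makes the on/off
  asymptotes coincide.
* Full-scale game benchmarks (tens of millions of frames, external ROMs)
  are intentionally out of scope.
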