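# sdqn — directly trained spiking deep Q-networks with potential-based layer normalization

Deep spiking convolutional networks lose their signal as depth grows: with
zero-mean random weights of variance `D(W)`, the sub-threshold membrane
potential of a leaky integrate-and-fire (LIF) neuron that has integrated
presynaptic steps `0..t` has variance

    D(u[t+1]) = D(W) * sum_i psi(i, t) * E[o_i],    psi(i, j) = (1 - alpha)^2 * alpha^(2*(j - i))

and its firing probability is bounded by `eps * (presynaptic spike mass)`
with the signal-loss ratio `eps = D(W) / (2 * V_th^2)`. For conventional
fan-in-scaled initializations `eps << 1`, so the expected spiking activity
shrinks geometrically with every layer — a randomly initialized spiking DQN
is almost silent past its first conv layer, and a silent network carries no
gradient signal for reinforcement learning.

This package implements that analysis and its remedy, **potential-based
layer normalization (pbLN)**: at every simulation step the post-synaptic
potential of a conv layer is standardized jointly over its `C*H*W` elements,

    x_hat = (x - mean(x)) / (sd(x) + eps_0),
    u[t+1] = alpha * u[t] + (1 - alpha) * (lambda * x_hat + beta),

with a learnable per-channel scale/shift initialized at
`lambda = V_th - V_reset`, `beta = V_reset`, so a +1-sigma input drives
exactly threshold. Around this core the package provides everything needed
to train and probe such networks on a desktop CPU:

* `lif_params()`, `lif_step()`, `run_trace()` — discrete LIF dynamics with
  Heaviside spiking and hard reset;
* `sdqn_network()`, `network_forward()` — spiking conv/FC stacks
  (default: the DQN `c32k8-c64k4-c64k3` architecture) with a time-averaged
  Q readout and constant-current pixel encoding;
* `network_backward()`, `surrogate_grad()` — surrogate-gradient
  backpropagation through layers and time, verified against central finite
  differences of a smooth relaxed network;
* `psi()`, `epsilon_ratio()`, `predicted_potential_variance()`,
  `spike_mean_bound()`, `monte_carlo_layer()`, `verify_theory()` — the
  closed-form variance/bound predictors and their Monte-Carlo oracle;
* `depth_profile()`, `potential_trace_report()` — firing-fraction and
  membrane-trace diagnostics that exhibit the vanishing and its rescue;
* `catch_env()`, `sdqn_train()`, `evaluate_policy()` — a seeded,
  self-contained pixel catch game plus the full DQN loop (replay, target
  network, epsilon-greedy, Adam), reproducible bit-for-bit under a seed.

It is written for computational-neuroscience and neuromorphic-RL
practitioners who want a transparent, dependency-light reference
implementation to study spiking-network trainability, not a general
deep-learning runtime.

## Worked example

Watch spike features vanish with depth on a randomly initialized
full-architecture network, and pbLN restore them (10 paired runs, shared
weights and frames):

```r
library(sdqn)
net <- sdqn_network(n_actions = 10, seed = 1)   # c32k8-c64k4-c64k3 + FC 512
prof <- depth_profile(net, n_runs = 10, seed = 1)
attr(prof, "summary")[, c("layer", "pbln", "firing_fraction", "firing_fraction_sd")]
#>   layer  pbln firing_fraction firing_fraction_sd
#> 1 conv1 FALSE      0.06607031        0.001282694
#> 2 conv1  TRUE      0.17571094        0.001268553
#> 3 conv2 FALSE      0.00000000        0.000000000
#> 4 conv2  TRUE      0.20682870        0.003287254
#> 5 conv3 FALSE      0.00000000        0.000000000
#> 6 conv3  TRUE      0.25475128        0.005038422
#> 7   fc1 FALSE      0.00000000        0.000000000
#> 8   fc1  TRUE      0.00000000        0.000000000
```

Without normalization only ~7% of conv1 neurons ever fire in a 16-step
window and the deeper conv layers are completely silent; with pbLN every
conv layer keeps 18–25% of its neurons active. The closed-form theory
predicts both regimes:

```r
epsilon_ratio(weight_var = 1 / (3 * 256), v_th = 0.5)   # conv1 fan-in 256
#> [1] 0.002604167                                       # eps << 1: vanishing
cfg <- layer_ensemble_config(n_pre = 10, weight_var = 0.5, spike_means = 0.3,
                             alpha = 0.5, T = 8, n_trials = 1e5, seed = 1)
mc <- monte_carlo_layer(cfg)
round(head(mc[, c("step", "var_pred", "var_emp", "spike_mean_emp", "spike_bound")], 3), 4)
#>   step var_pred var_emp spike_mean_emp spike_bound
#> 1    1   0.3750  0.3758         0.1889           3
#> 2    2   0.4688  0.4683         0.2186           6
#> 3    3   0.4922  0.4959         0.2282           9
```

Train the desk-scale spiking DQN on catch (2×10⁴ steps, ~2 minutes on one
CPU) and compare with the exact random-policy value (a random paddle
catches about one drop in seven):

```r
cfg <- smoke_run_config(seed = 1)
built <- config_build(cfg, seed = 1)
res <- sdqn_train(built$env, net = built$net,
                  config = do.call(train_config, cfg$train))
mean(tail(res$log$reward, 20))        # final-20-episode mean reward
#> [1] 0.2
catch_random_policy_value(21, 3)      # exact uniform-random expectation
#> [1] -0.7142857
```

A command-line wrapper over the same functions ships at
`inst/cli/sdqn.R` (`train`, `evaluate`, `diagnose-firing`, `verify-theory`,
`trace-potential`).

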