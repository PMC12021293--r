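# metaplast

Meta-learning of synaptic plasticity rules in recurrent spiking networks.

Plasticity rules measured at single synapses rarely produce the network
behaviour they are meant to explain. `metaplast` searches in the opposite
direction: it treats the plasticity rule itself as the unknown, embeds
parameterized candidate rules in recurrent excitatory/inhibitory networks of
conductance-based leaky integrate-and-fire neurons (an inner simulation
loop), and optimizes the rule parameters with CMA-ES against a loss that
scores the *network's* behaviour (an outer evolutionary loop). It is aimed
at computational neuroscientists who want to discover, analyze or stress-test
candidate rules rather than hand-tune them.

## What is inside

* **Spiking network core** (`build_network`, `simulate_episode`,
  `step_network`): two network variants — fixed threshold with absolute
  refractoriness, and adaptive threshold with an NMDA-like composite
  conductance — integrated with forward Euler at 0.1 ms, driven by Poisson
  inputs, with spike, rate, membrane and weight recording. A plain-R
  reference stepper reproduces the compiled core spike-for-spike.
* **Three rule parameterizations** (`small_poly_rule`, `big_poly_rule`,
  `mlp_rule`): a six-parameter pair-based STDP rule
  (dw = α·S_pre + β·S_post + γ·S_post·x_pre + κ·S_pre·x_post, learnable
  trace time constants optimized on the log scale), a 21-parameter
  separable polynomial over weight, low-passed voltage ⟨V⟩ and codependent
  currents C_E/C_I, and an 11-parameter partially frozen multilayer
  perceptron (hidden layers 6→50→4, only the output layers and a shared
  learning rate are tuned).
* **Tasks** (`stability_task`, `familiarity_task`): firing-rate homeostasis
  at a 10 Hz target, and familiarity detection (respond more strongly to a
  repeatedly seen input subset than to a novel one), with randomized
  per-trial networks and explicit, switchable loss terms.
* **Outer loop** (`cmaes_init`/`cmaes_ask`/`cmaes_tell`,
  `run_meta_learning`): standard (μ/μ_w, λ)-CMA-ES with covariance
  snapshots, a deterministic seed ladder and resumable artifacts.
* **Analysis & theory** (`pre_post_curve`, `episode_summary`,
  `meanfield_rate`, `solve_for_target`): pairing-protocol curves, episode
  statistics (ISI CV, silent fractions, weight bimodality/saturation), and
  closed-form mean-field fixed points with stability flags for pair-based
  rules.
* **Experiment plumbing** (`experiment_config`, `run_experiment`, a thin
  CLI at `inst/cli/metaplast`): YAML configs, JSON rule serialization, CSV
  trajectories, reproducible from the master seed alone.

## Worked example: a homeostatic inhibitory rule from mean-field theory

Build an I→E rule whose mean-field fixed point is 10 Hz, then watch it
steer a 500-neuron network there:

```r
library(metaplast)

rule <- solve_for_target("ie", target_rate = 10, free = "kappa",
                         rule = small_poly_rule(alpha = -0.01, tau_post = 100),
                         counterpart_rate_hz = 20)
meanfield_rate("ie", rule, counterpart_rate_hz = 20)
#> <meanfield_prediction: ie>
#>   fixed-point rate: 10.000 Hz
#>   H = kappa*tau_post + gamma*tau_pre = 0.001 s
#>   stable: TRUE (alpha<0: TRUE, denominator>0: TRUE)

net <- build_network("vogels", topology_config("vogels", "desk"), seed = 1)
res <- simulate_episode(net, rule_assignment(ie = rule), duration_ms = 20000,
                        input_seed = 2, eval_windows = cbind(13000, 20000))
res
#> <episode_result: 20000 ms, mean E rate 8.58 Hz, mean I rate 28.27 Hz>
round(res$eval_rates, 2)   # mean E rate over the final third
#> [1] 9.08
```

The depressing-everywhere pairing protocol of this rule (every pre/post
pair weakens the inhibitory weight, yet the network-level fixed point is
stable — the non-Hebbian α term carries the homeostasis):

```r
as.data.frame(pre_post_curve(rule, dt_grid = c(-20, -10, 0, 10, 20)))
#>   dt_ms            dw
#> 1   -20 -0.0018126925
#> 2   -10 -0.0009516258
#> 3     0 -0.0100000000
#> 4    10 -0.0100000000
#> 5    20 -0.0100000000
```

To *discover* such a rule instead of deriving it, run the outer loop
(minutes on one core at desk scale):

```r
run <- run_meta_learning(stability_task(), space = "small_poly", seed = 101)
run$best_rule$ie                    # the learned six-parameter rule
correlation_matrix(run$es_state)    # parameter interdependencies
```

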