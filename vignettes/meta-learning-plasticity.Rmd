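---
title: "Meta-learning synaptic plasticity rules in recurrent spiking networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Meta-learning synaptic plasticity rules in recurrent spiking networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaplast)
```

## The problem

Synaptic plasticity rules are usually fit to single-synapse experiments and
then fail to produce the network-level behaviour they are supposed to
explain.  `metaplast` inverts the direction of inference: it searches the
space of candidate plasticity rules directly for rules that produce a
desired *network* behaviour.  Two nested loops do the work:

* **Inner loop** — a recurrent network of conductance-based leaky
  integrate-and-fire neurons (separate excitatory and inhibitory
  populations, sparse random connectivity, Poisson input) is simulated
  while one or more synapse blocks (E→E, E→I, I→E, I→I) evolve under a
  parameterized plasticity rule.  A loss function scores the resulting
  dynamics.
* **Outer loop** — CMA-ES (Covariance Matrix Adaptation Evolution
  Strategy) maintains a Gaussian search distribution over the rule's
  parameter vector θ, samples a generation of candidate rules, evaluates
  each in several randomized networks, and updates its mean and covariance
  from the loss ranking.

Spiking networks are not usefully differentiable over behavioural
timescales, which is why the outer loop is gradient-free.

## Network models

Two variants are implemented, both integrated with forward Euler at
`dt = 0.1` ms.

**Fixed-threshold variant** (`variant = "vogels"`).  Membrane dynamics

$$\tau_m \dot V_j = -(V_j - V_\mathrm{rest})
  - g^\mathrm{AMPA}_j (V_j - E_\mathrm{AMPA})
  - g^\mathrm{GABA}_j (V_j - E_\mathrm{GABA}),$$

with $\tau_m = 20$ ms, $V_\mathrm{rest} = -60$ mV, $E_\mathrm{AMPA} = 0$ mV,
$E_\mathrm{GABA} = -80$ mV, threshold $-50$ mV, reset to rest and a 5 ms
absolute refractory period (the membrane is clamped, not integrated).
Conductances decay exponentially (5 ms AMPA, 10 ms GABA) and jump by the
synaptic weight at each presynaptic spike; weights are unitless.  Full
scale: 8000 E, 2000 I neurons, 2% recurrent connectivity, 5000 Poisson
inputs at 5% connectivity and 7 Hz.

**Adaptive-threshold variant** (`variant = "zenke"`).  Same membrane
equation with $V_\mathrm{rest} = V_\mathrm{reset} = -70$ mV.  The threshold
jumps by 100 mV at each spike and relaxes to $-50$ mV with time constant
`tau_th`; the excitatory conductance is the composite
$g_E = a\,g_\mathrm{AMPA} + (1-a)\,g_\mathrm{NMDA}$ with $a = 0.23$, where
the NMDA conductance low-passes the AMPA conductance with a 100 ms time
constant.  Full scale: 4096 E, 1024 I, 10% recurrent connectivity, 5000
inputs at 5%.  `tau_th` is nowhere printed in the sources this model
follows; the default is 5 ms (fast threshold adaptation, the relevant
order of magnitude) and it is an explicit configuration field.

Self-connections are excluded (standard practice; autapses add pathologies
and nothing else).  External input connects to both populations at the
same density.  There are no synaptic delays.

### Integration conventions

All tests and analyses depend on one fixed scheme, mirrored exactly by the
plain-R reference stepper `step_network()` and verified spike-for-spike
against the compiled core:

1. membrane update from start-of-step conductances (forward Euler);
2. threshold crossing → spike, reset, refractory/threshold bookkeeping;
3. auxiliary low-pass variables update;
4. exact exponential conductance decay (Euler relaxation for NMDA);
5. this step's spikes (external and recurrent) increment target
   conductances — spike effects land at the end of the step in which the
   spike occurs;
6. plasticity: all pre-triggered updates, then all post-triggered updates;
   synaptic traces are read *before* any +1 increment of this step and
   bumped afterwards.  Weights are hard-clipped to their block bounds
   (default `[0, 10]`) after every single update.

Traces decay by exact exponentials (event-driven), so pair-based rule
trajectories agree with the event-driven closed form to floating-point
precision rather than to Euler order; the membrane itself carries the
usual O(dt) Euler error, which the tests' tolerances reflect.

## Rule parameterizations

Three search spaces of increasing expressivity share the same
spike-triggered update structure $\dot w_{ij} = S_i(t)\,f_\mathrm{pre} +
S_j(t)\,f_\mathrm{post}$:

* **Pair-based polynomial** (6 parameters).  $\Delta w = \alpha + \kappa\,
  x_\mathrm{post}$ on a presynaptic spike and $\Delta w = \beta + \gamma\,
  x_\mathrm{pre}$ on a postsynaptic spike, with learnable trace time
  constants.  α and β are non-Hebbian (single-spike) amplitudes, γ and κ
  Hebbian (pair) amplitudes.  Time constants are optimized as natural
  logarithms so any real search vector decodes to a valid rule.
* **Separable polynomial** (21 parameters).  Pre- and post-factors are
  products of one-variable polynomial factors in the weight (quadratic),
  the 100 ms low-passed membrane potential ⟨V⟩, codependent current terms
  $C_E$ (10 ms) and $C_I$ (100 ms low-pass of $g_E(E_E - V)$ and
  $g_I(E_I - V)$), and fixed 10/100 ms pre- and post-traces, with a cubic
  term on the long postsynaptic trace.  Separability keeps the parameter
  count linear in the number of synaptic variables.  Restricted to the
  pair-based submanifold it reproduces pair-based trajectories exactly
  (a reduction the tests check to 1e-10).
* **Partially frozen MLP** (11 parameters).  Two feedforward networks
  (pre- and post-spike) over six synaptic variables with hidden layers
  6→50→4 (sigmoid), whose weights are drawn once from
  $U(\pm 1/\sqrt{n_\mathrm{inp}})$ under a recorded `frozen_seed` and
  never trained; tunable are only the 4+1 output weights/bias per network
  and one shared learning rate.  Hidden units carry no bias terms — with
  biases the tunable count could not be 11, so the bias-free reading is
  the consistent one.  The pre-network reads the *long* presynaptic and
  *short* postsynaptic trace; the post-network the reverse.

The quiescent rule (all amplitudes zero) changes no weight on any episode
and is the optimizer's starting point — starting from silence stabilizes
the early meta-iterations because no candidate can destroy the network
before it is scored.

## Tasks and losses

The loss functions are this package's own design: the behavioural goals
(settle at a target rate; respond more to familiar than to novel input)
are fixed by the problem, but no closed loss form is prescribed anywhere,
so each term is explicit and switchable.

**Stability.**  Each trial draws the external rate from U[4, 10] Hz, the
mean initial weight of every block from U[0.05, 0.5] (individual weights
uniform within ±50% of the mean) and fresh connectivity.  The loss is the
mean over 500 ms evaluation windows covering the final half of the episode
of $((r_E - r^\ast)/r^\ast)^2$ with $r^\ast = 10$ Hz, plus
$\lambda\,\lVert\theta_\mathrm{ampl}\rVert_1$ (λ = 0.01; log time
constants excluded from the penalty).  L1 regularization nudges the search
toward sparse, interpretable rules.

**Familiarity.**  A familiar subset (10% of input neurons) is presented
repeatedly at 4× the background rate; after a break, a disjoint novel
subset and then the familiar subset are probed with plasticity frozen, so
the probes measure the learned state rather than ongoing learning.  The
loss is a hinge $\max(0, r_\mathrm{nov} + m - r_\mathrm{fam})/m$ with
margin $m = 5$ Hz, plus a plausibility penalty for mean excitatory rates
outside [2, 30] Hz, plus the same L1 term.

Diverged or silent-degenerate episodes map to a fixed penalty cap (ten
times the all-silent loss: 10 for stability, 20 for familiarity), which
keeps CMA-ES's ranking well defined.  The cap is a constant so that every
flagged episode compares equal.

**Candidate evaluation** averages the loss over `n_trials = 4` randomized
trials (the defensible range is 4–10; 4 keeps a desk-scale generation
under a minute).  All candidates of one generation share the same trial
seeds (common random numbers), so their ranking reflects the rules rather
than luck in the network draw.

## The outer loop

`cmaes_init()` / `cmaes_ask()` / `cmaes_tell()` implement the standard
(μ/μ_w, λ)-CMA-ES with rank-one and rank-μ covariance updates and
cumulative step-size adaptation; the generation size defaults to twice
the parameter count (12 for the pair-based space) and σ₀ = 0.3 in encoded
units — large enough that amplitude perturbations of order 0.1–0.3 are
reachable in a few generations, small enough that most of the first
generation is not penalty-capped.  Degenerate generations (all losses
equal) advance the generation counter without moving the mean, since
ranks carry no information.  A non-PSD covariance (numerically possible
after aggressive updates) is repaired by eigenvalue flooring with a
warning.

Runs stop at `max_iter` or once the generation's best candidate loss has
been below `stop_loss = 0.05` twice in a row — at that level the rate sits
within sampling error of the target and further iterations only shrink σ.
The learned rule is decoded from the final distribution mean; the
best-ever candidate is also reported.  The covariance matrix is
snapshotted at iterations 10, 15 and 20 (the informative window before
the loss plateaus, after which correlations saturate toward ±1); its
correlation form (`correlation_matrix()`) is what reveals parameter
interdependencies, e.g. the anti-correlation of the two non-Hebbian
amplitudes in successful homeostatic rules.

Seed ladder: master seed → per-iteration ask seed and trial-seed base →
per-trial seeds, all derived with `derive_seed()`; a whole run is a pure
function of its configuration and master seed.

## Mean-field predictions

For a single pair-based rule active in isolation, setting the expected
drift to zero under independent Poisson firing gives closed-form
fixed points (`meanfield_rate()`), e.g. for I→E
$r^\ast_\mathrm{exc} = -\alpha r_\mathrm{inh} / (\beta + H r_\mathrm{inh})$
with $H = \kappa\tau_\mathrm{post} + \gamma\tau_\mathrm{pre}$ (τ in
seconds; the ms→s conversion is centralized), stable when $\alpha < 0$
and the denominator is positive.  The E→E and I→I forms both pin the
*inhibitory* rate via $-(\alpha+\beta)/H$; they are implemented exactly
as stated, not reinterpreted.  `solve_for_target()` inverts these
expressions for one free amplitude and is validated in simulation: a
solved I→E rule drives the desk network to its 10 Hz fixed point.

Two assumptions of the derivation matter in practice at small scale.
First, it assumes *uncorrelated* pre/post firing: with a 10 ms
postsynaptic trace, the correlation between inhibitory spiking and the
recent excitatory trace shifts the realized fixed point by several Hz on
the desk network, while a 100 ms trace averages the correlation out — the
validation therefore uses `tau_post = 100` ms.  Second, inhibitory
homeostasis can only *reduce* the rate: the unplastic baseline must
exceed the fixed point for the prediction to be reachable.

## Scaled-down study conditions

The desk preset (400 E, 100 I, 500 inputs, 10 s episodes) exists so that
a complete meta-learning run takes minutes, not days.  Densities are the
one place where literal proportionality is wrong: with 100 inhibitory
neurons, 2% connectivity gives a Binomial(100, 0.02) I→E in-degree, so
~13% of excitatory neurons receive *no* inhibition and fire at their
uninhibited rate regardless of any I→E rule — the 10 Hz target becomes
structurally unreachable.  The desk preset therefore uses 10% recurrent
connectivity (in-degrees of order 10) for both variants, preserving the
operating point instead of the literal density; full scale keeps the
published densities.

Per-trial randomization (external rate, initial mean weights,
connectivity) is a *training* device: averaging the loss over randomized
networks selects rules that work across conditions rather than for one
draw.  The randomization deliberately includes low-drive draws on which no
inhibitory rule can raise the rate to target — useful pressure during
training, but not a meaningful single-episode test of a learned rule.
Learned rules are therefore *evaluated* on the preset's canonical default
network (mean weight 0.275 per block, 7 Hz input) with fresh connectivity
and input seeds.

What desk-scale results do and do not show: the generator reproduces the
qualitative regime (conductance-based balanced dynamics, randomized
initial conditions, Poisson drive) and the full meta-learning loop, but
finite-size fluctuations are larger, correlations stronger, and the
specific learned parameter values are not expected to transfer to full
scale — only the structure of the solutions (e.g. α < 0 with a
compensating Hebbian term for I→E homeostasis) is.

## Numerical and design choices

* `dt = 0.1` ms everywhere; durations must be multiples of `dt`.
* Coincident pre+post spikes in one step: pre-update applied first, then
  post; all same-step events read pre-bump traces.  Covered by a
  dedicated tie-break test.
* Weight bounds `[0, 10]` on every plastic block by default (per-block
  configurable); clipping is hard, applied after each single update, and
  idempotent.
* Pairing-protocol curves default to a single isolated pair per delay
  with clamps `w = 5`, `⟨V⟩ = −60 mV`, `C_E = C_I = 0`; the clamps are
  attached to every curve as metadata because the aux-dependent spaces
  are not identified by the pair protocol alone.  A pair-train mode is
  available.
* Poisson inputs are per-bin Bernoulli events, generated as a per-bin
  Binomial count plus a uniform draw of distinct neurons (identical
  distribution, far fewer RNG calls).
* Episode sizes in the test suite: 0.2–2 s for unit tests, 6–20 s for the
  mean-field validation, 10 s episodes with ≤ 40 meta-iterations for the
  end-to-end meta-learning check.

## Known limitations

* No synaptic delays, no GPU path, and no attempt to reproduce any
  specific previously published learned rule parameters.
* Mean-field theory covers only the pair-based space.
* CMA-ES is a local strategy: distinct runs find distinct, degenerate
  solutions; the covariance snapshot is a heuristic lens on the loss
  landscape, not an identified posterior.
* The familiarity task at desk scale is bistable across trials (silent
  vs. active networks depending on the drawn weights), which makes its
  loss landscape noisier than the stability task's.
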