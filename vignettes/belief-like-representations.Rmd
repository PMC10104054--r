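---
title: "Belief states, value RNNs, and how we measure belief-likeness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Belief states, value RNNs, and how we measure belief-likeness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beliefrnn)
```

## The problem

In Pavlovian trace conditioning an animal hears/smells a cue and receives a
reward after a variable delay. Classical temporal-difference (TD) models of
dopamine assume the agent knows the state of the world at every moment; in
these tasks it does not. The delay to reward is probabilistic, rewards may be
omitted, and reward sizes may depend on a hidden block identity. The normative
response to partial observability is to filter: maintain a Bayesian posterior
over hidden states (the *belief state*) and learn values as a linear function
of that posterior. An alternative is to let a recurrent network learn its own
state representation end-to-end from observations while being trained only to
predict value. This package implements both routes and a battery of probes
that ask how belief-like the learned recurrent representation is.

## Tasks and their micro-state formulation

Two task families are implemented as generative simulators (`generate_session`):

* **Starkweather tasks.** Each trial is an intertrial interval (ITI), one
  odor, an interstimulus interval (ISI), then a unit reward. The ISI is a
  discretized Gaussian on 6..14 steps (mean 10, sd 2.5, one step = 200 ms);
  the ITI is 10 steps plus a Geometric(1/8) tail. Task 1 rewards every trial;
  Task 2 omits the reward on 10% of trials.
* **Babayan task.** Every trial is rewarded, but the magnitude (1 or 10) is
  set by a hidden block identity resampled uniformly every 5 trials; ISIs are
  uniform on {9, 10, 11}. Probe sessions mix in intermediate magnitudes
  {2, 4, 6, 8} at low rates (standard blocks keep ~90% of trials).

Because the delays are not memoryless, the semi-Markov process is converted
into a Markov chain over *micro-states*: one clock state per possible elapsed
step, with hazard exits. For the Starkweather tasks this gives K = 25 states
(14 ISI + 11 ITI); the reward hazard is `h_t = p_t / (1 - F_{t-1})`, which
equals 1 at the last possible reward time. For the Babayan task each block
has its own 22-state copy; the composite belief is the 44-vector
`[p b1, (1-p) b2]` where `p` is the block posterior, replaced by the
reward-magnitude likelihood `f(r)` whenever a reward is observed (likelihood
sd 0.001, so any observed magnitude pins the block almost surely; `f(5.5)`
= 0.5 by symmetry).

Design choices that the task definitions leave open, fixed here once:

* The geometric ITI tail counts from 1 (`t_ITI = 10 + G`, `G >= 1`), so the
  shortest realizable ITI is 11 steps. This is forced by the micro-state
  chain: after a reward the state needs 10 deterministic steps to reach the
  absorbing ITI state, whose odor hazard then fires at the earliest one step
  later.
* "Discretized Gaussian" means the Normal density evaluated at the integer
  support and renormalized.
* Sessions begin in the absorbing ITI state, and that is also the initial
  belief; the Babayan block prior starts at 0.5.
* Probe-block mixture weights: 45% per standard block, 2.5% per intermediate
  magnitude.
* On omission trials there is no hidden "omission ISI": the true state
  re-enters the ITI progression at the odor, which is exactly what the
  Task 2 odor transition (90/10 split between ISI entry and ITI entry)
  assumes. Ground-truth labels therefore stay consistent with the emission
  model, and the test suite checks label/observation consistency exactly.
* The trial-based generator is deliberately *not* identical to the
  micro-state chain: after an omission trial it appends the next trial's
  full ITI to the omission trial's silent interval, whereas the chain's
  odor hazard would already be live. The belief model (which follows the
  chain) is therefore a mild, deliberate approximation of the generator on
  Task 2; the trial-wise task definition and the micro-state space carry
  this mismatch by construction. Tests that assert exact model self-consistency
  (Bellman values, zero-mean TD errors) run on observation streams sampled
  from the chain itself.

## Beliefs and values

`run_beliefs` implements the filter `b_t(k') ∝ Σ_k O_o(k',k) T(k',k)
b_{t-1}(k)` with observations attached to transitions. An observation that is
impossible under the model raises an error rather than renormalizing
silently — a mismatch between a session and a space should fail tests, not
pass quietly. (The dynamics probes use a continuity extension at
zero-likelihood observations; see below.)

Value readouts are fit by least-squares TD (`lstd_fit`):
`w = D^{-1} d`, `D = Σ z_t (z_t - γ z_{t+1})'`, `d = Σ r_{t+1} z_t`, γ = 0.93
throughout. Two conventions deserve emphasis:

* **Reward/index pairing.** TD errors are attributed to transitions:
  `δ_t = r_{t+1} + γ V_{t+1} - V_t`. The alternative pairing (reward indexed
  with the same step as the post-observation representation) makes the
  converged TD error at reward times identically zero — the post-reward state
  would absorb its own reward — so no reward-time RPE pattern could exist
  under it. With the transition pairing, the fitted belief model's RPE at
  reward is the classical quantity: reward plus discounted post-reward value
  minus pre-reward value.
* **Intercept.** `lstd_fit` appends a constant feature by default so the
  offset w0 is estimated jointly. Beliefs sum to one, which puts the constant
  inside the feature span and makes the augmented system exactly singular;
  belief-based fits therefore use `intercept = FALSE` (w0 is absorbed into
  w). The rank check fails loudly otherwise, and a ridge option exists for
  deliberately degenerate representations.

With these conventions the belief model's reward-time RPE curves are fully
determined by the hazard and the omission posterior: in Task 1 the hazard
reaches 1 at the last delay, so the latest reward is fully predicted (zero
RPE) and the curve *decreases* with reward time; in Task 2 the growing
omission belief depresses the pre-reward value late in the interval, so late
rewards regain surprise and the curve turns *up* at long delays. These are
the directions the micro-state model necessarily produces (the test suite
asserts them), and they are what the reward-time analyses in this package
report.

## The value RNN

The representation learner is a standard GRU (hidden size H, inputs
`o_t = (odor, reward)`) with a linear value readout, trained by semi-gradient
TD: the loss is the squared TD error with the bootstrap target held constant
under differentiation. Training follows a fixed protocol: episodes of 20
concatenated trials (50 for the Babayan task) drawn as disjoint consecutive
blocks from a 10,000-trial session, shuffled each epoch, batches of 12
episodes, Adam at learning rate 0.003, at most 150 epochs, early stopping
after 4 consecutive epoch-loss increases, and the parameters of the
best-loss epoch retained. Hidden states reset to zero at episode starts, and
the last step of an episode contributes no TD term. No hyperparameter search
sits behind any of these numbers.

The forward pass and backpropagation-through-time are implemented in
RcppArmadillo (`src/gru.cpp`) with episodes padded to a common length and
masked, which keeps a full 150-epoch training of an H = 50 network on a
10,000-trial session in the low minutes on one CPU core. The plain-R
`gru_step` mirrors the cell definition and is cross-checked against the
compiled path in the tests (to 1e-10 on random parameters), alongside a
separately written per-unit reference implementation.

Initialization:

* **Default (trainable) networks**: all GRU weights, biases, and the readout
  i.i.d. uniform on (-1/√H, 1/√H).
* **Echo-state networks (ESNs)**: biases zero, each gate's recurrent matrix
  an *independent* random orthogonal matrix scaled by a gain, input weights
  Xavier-uniform with bound √(6/(2+H)), and the whole recurrent/input/bias
  parameter set frozen during training (only the value readout learns). The
  per-gate orthogonal reading is deliberate: the null-input linearization of
  the cell then has spectral radius 0.5 + gain/4, so transients lengthen
  with gain and stability is lost at gain 2, which is the phenomenology these
  reservoirs are meant to expose (long memories near gain 1.9, no return to
  baseline above 2). A single stacked semi-orthogonal matrix would instead
  scale each gate by ~1/√3 and push the instability to gain ≈ 3.5.

## Probing belief-likeness

All fitted probes use two fresh 1,000-trial sessions (fit and evaluation) and
one fixed recipe:

* **Noise injection** (`inject_noise`): RNN traces are deterministic, so
  zero-mean Gaussian noise with sd 1% of each unit's sd (40 dB SNR) is added
  before any regression or decoding, fresh per session. Beliefs stay
  noise-free, as do the PCA and dynamics analyses.
* **Belief R²** (`belief_r2`): multivariate regression from the
  (noise-injected) representation plus constant onto the belief trace, fit on
  session one by a QR least-squares solve (not the literal normal-equations
  inverse; they agree to 1e-8 but the factorization tolerates collinear
  units), scored on session two as one minus the ratio of total residual
  variance to total belief variance. R² is invariant to invertible affine
  transformations of the representation, which the tests assert.
* **State decoding** (`fit_state_decoder`, `decoder_loglik`): multinomial
  logistic regression from the standardized representation to the
  ground-truth micro-state, penalized by `1/(2C)·||W||²` (C = 1, intercepts
  free), fit by L-BFGS with a 1e4 iteration cap and a non-convergence flag
  recorded in the result. Held-out performance is the mean log-likelihood of
  the true states; the beliefs themselves, used directly as probabilities,
  are the ceiling under the generative model. Classes absent from the fit
  session are scored at a 1e-12 floor, with clamp counts reported. For the
  Babayan task the first trial of every block is excluded, since the beliefs
  are only a proper ceiling when the block identity has been revealed.
* **PCA** (`pca_top2`): share of total variance captured by the top two
  principal components of the mean-centered, noise-free hidden-state trace.
* **Dynamics** (`find_fixed_points`, `memory_duration`): null-input fixed
  points found by iterating from 20 states sampled just after odor/reward
  observations, with the step-size criterion ε = 1e-5, candidates merged
  within distance 1e-3, and a 1,000-step cap. After the ε criterion is met,
  iteration continues to a 1e-14 squared step so that every seed flowing
  into one attractor lands on the same point instead of stranding as
  scattered slow points; marginally stable maps keep their ε-level
  candidate. Odor/reward memory starts at a fixed point, applies one
  observation, and reports the first step whose squared distance back to the
  fixed point drops below 1e-3. For belief maps, an observation with zero
  likelihood at the probe state (a reward delivered at the ITI fixed point)
  is handled by the continuity limit — the update applied to a uniform prior
  over the emitting states — which for a reward is exactly the point mass at
  the ITI entry state; `belief_step` itself still errors. Under these
  definitions the Task 2 belief map returns in 15 steps after an odor and 11
  steps after a reward, deterministically.

## What the simulators do and do not emulate

The generators reproduce the discrete-time structure the models were built
on: geometric-plus-minimum ITIs, discretized-Gaussian or uniform ISIs,
omissions, hidden blocks, probe magnitudes. They do not emulate licking or
other behavior, scalar (Weber-law) timing noise, continuous time, or
session-level nonstationarity in real animals. Tests passing on these
simulations therefore validate the computational claims (filter correctness,
TD fixed points, representation probes), not any claim about biological
dopamine beyond the qualitative RPE patterns the models were designed to
capture.

## Problem sizes used by the checks

The package's own evaluation (tests and `scripts/acceptance.R`) trains on
full 10,000-trial sessions at H = 50 but with reduced cohort sizes (2–3
trained networks per task rather than 12; 12 untrained initializations,
which are cheap). The acceptance script keeps the full 150-epoch cap; the
test suite caps training at 100 epochs (early stopping usually fires near or
below that anyway). Property tests use smaller sessions (50–4,000 trials)
and hidden sizes (2–50) chosen so the whole suite stays in the tens of
minutes on one core. Cohort means over 2–3 networks carry real sampling
spread — individual trainings occasionally converge to collapsed,
low-dimensional representations that still predict value well — and the
reported per-cohort standard errors make that spread explicit rather than
hiding it.

## Known limitations

* The block posterior of the Babayan belief model depends only on the most
  recent reward (by construction), so it cannot count trials within a block;
  decoding analyses exclude block-initial trials for exactly this reason.
* Early stopping on the noisy epoch loss occasionally halts Babayan training
  in under ten epochs; the retained best-epoch parameters are then close to
  initialization. This is inherent to the stated stopping rule at this
  scale and shows up as cohort spread.
* Task 1 beliefs are undefined after 14 post-odor null steps (no omissions
  exist in its generative model); the dynamics probes therefore make no
  belief-side claim there, while RNN maps remain well defined.
* `find_fixed_points` characterizes attractors reachable from
  post-observation states, not the full fixed-point landscape; no
  linearization or optimization-based slow-point search is attempted.
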