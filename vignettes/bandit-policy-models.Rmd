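---
title: "Explaining recurrent choice models with explicit cognitive models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Explaining recurrent choice models with explicit cognitive models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`banditlens` studies how a high-capacity black-box model of sequential
choice can be characterised by explicit cognitive models. This vignette
documents the models, the synthetic data they are exercised on, the
numerical choices, and the limits of what the pipeline can show.

## The task and its simulator

The environment is a restless four-armed bandit. Each arm's payoff follows
an independent Gaussian random walk with per-trial standard deviation
`drift_sd` (default 2.8 points), bounded in `[1, 98]` points, initialised
uniformly within the bounds. Episodes last 150 trials by default, and each
trial is missed (no action, no reward) with probability
`miss_probability`.

Boundary behaviour is a genuinely open design point: the drift could be
clipped, resampled, or reflected at the bounds. We reflect. Clipping
accumulates probability mass exactly at the edges and shrinks the realised
per-step standard deviation whenever the walk visits them; reflection
preserves the increment distribution away from the bounds and is the
standard construction for bounded random walks. The acceptance suite
verifies that the realised increment sd over a long unconstrained walk is
2.8 to within ±0.05.

Three default payoff structures are generated from three fixed, documented
seeds (101, 202, 303); any number can be generated with
`generate_payoff_structure()`.

`miss_probability` defaults to 0.01. A window of four context trials plus a
target spans four inter-trial gaps, so the probability that a window
contains a skipped round is `1 − (1 − p)⁴ ≈ 3.9%` at `p = 0.01` — the
calibration target for the missed-trial process. Rewards are real-valued
internally and rounded to integer points only on CSV export.

## The synthetic population

The analysis assumes behaviour is a mixture of reward-driven learning and
reward-oblivious pattern following. The generator makes that mixture
explicit, with four agent kinds:

- **q_learning** — delta-rule value learning with softmax choice. Per-agent
  parameters are drawn `α ~ U[0.1, 0.6]` and `β ~ U[0.05, 0.3]`. On a
  1–98-point reward scale, value differences between arms are tens of
  points, so inverse temperatures of this order span near-greedy to
  moderately noisy choice.
- **pattern** — deterministic motor patterns: constant (one fixed option),
  alternating (two fixed options), or cycling 1→2→3→4→1.
- **hybrid** — a synthetic-only construct: the agent learns values like a
  Q-learner but acts on them only when they are decisive, falling back to
  its motor pattern when the gap between the best and second-best value is
  below `value_gap_threshold` (drawn `U[5, 20]` points). This is the
  simplest mechanism producing agents that rely on patterns when rewards
  identify no clear best action.
- **random** — uniform choice; a noise floor.

The default mixture is 40% q_learning, 30% pattern, 20% hybrid, 10%
random. No empirical composition is available to calibrate against, so the
default is simply a population in which both explicit models have
substantial signal, chosen once and kept.

What the generator does *not* emulate: reaction times and deadline
dynamics beyond the Bernoulli miss process, learning-to-learn across the
session, individual parameter drift, and the noise level of human
populations. The last point matters for interpretation (see *Limitations*).

## Sequence datasets

Records are cut into K-step context windows with the following rules,
all implemented in `make_windows()`:

- missed trials are removed from the action stream first; windows are
  consecutive over the remaining trials, and a window whose span skips a
  removed trial is flagged `has_gap` (kept by default — the reward drift is
  slow, so a one-round gap barely stales the context; a `max_gap` filter is
  available and off by default, and evaluation-time exclusion is a config
  switch);
- training uses a sliding window (stride 1), so a gap-free 150-trial record
  yields 146 samples and the first prediction is for round 5;
- evaluation uses non-overlapping blocks of K + 1 trials (stride K + 1), so
  no trial is reused across evaluation samples. This is the only reading of
  "no sliding window at evaluation" that changes anything relative to the
  training extraction;
- trial indices are 1-based throughout.

Cross-validation splits are made over participants (default five folds):
models generalise to unseen individuals, not unseen time points of seen
individuals, and each participant is predicted exactly once across folds.

## The recurrent models

Both black-box models are single-layer LSTMs with 64 hidden units and a
4-way softmax readout from the final hidden state, trained by Adam
(learning rate 0.001, β₁ = 0.9, β₂ = 0.99) on mean categorical
cross-entropy. The exploratory model encodes each step as a 5-vector
(action one-hot + reward / 98, so all inputs lie in [0, 1]); the
reward-oblivious model receives the 4-vector one-hot only — its reward
invariance is structural, not learned, and is asserted exactly in the
tests. The cell is implemented in base R matrix operations inside the
package (forward pass, backpropagation through time, Adam), with gradients
verified against numerical differentiation to 1e-5 in the test suite.
Weights use uniform Glorot initialisation with the forget-gate bias at 1;
argmax predictions break ties toward the lowest action index,
deterministically. Given a seed, training is bit-reproducible.

Training configuration: the full-scale recipe is 300 epochs at batch 2048.
At this package's default problem sizes (hundreds of participants, tens of
thousands of windows) that batch size leaves the optimiser too few steps,
so the pipeline's desk-scale configuration is 50 epochs at batch 512
(~3,400 Adam steps on ~35k samples), which trains both models to a stable
loss in minutes on one CPU. Both knobs are plain arguments.

## The reward-oriented model

Q-learning with values initialised at 50 (the midpoint of the reward
range), delta-rule updates on non-missed trials only, and softmax choice
probabilities computed from the pre-choice values with max-subtraction for
numerical stability. The group-level (α, β) is fitted by pooling all
participants into one likelihood and minimising the summed negative log
probability of observed actions with L-BFGS-B from five random starts
(per-participant fitting is available but non-default). The search box is
α ∈ [0, 1], β ∈ (10⁻⁶, 1]: on this reward scale fitted inverse
temperatures sit near 0.03–0.3, so an upper bound of 1 is loose.
Accuracy uses the argmax of the pre-choice values, scored on non-missed
trials only; the first trial (an all-50 tie, broken to action 1) is
included but flagged so reports can drop it.

Parameter recovery is the module's core validation: the acceptance suite
generates 200 agents at (α = 0.3, β = 0.15), 150 trials each, and requires
recovery within ±0.05 and ±0.03 respectively; a consistency check verifies
that recovery error shrinks with data size, and uniform-random agents drive
the fitted β to its noise bound.

## Model comparison

Accuracy tables are computed per participant and per trial on prediction
sets aligned to identical (participant, trial) pairs — trials any model
cannot score (the first K rounds, evaluation-filtered gaps) are excluded
pairwise, and the per-trial participant count M adjusts accordingly.

The trial-wise similarity of two models is the fraction of participants on
which they agree in *correctness* — both correct or both wrong counts as
agreement. Note one formal wrinkle: written as a formula this is the mean
of the complement of the XOR of the two correctness indicators (an XNOR);
a bare XOR would measure disagreement. The implementation follows the
verbal definition (agreement), which is also the quantity whose self- and
symmetry properties the tests assert.

## Experimental simulations

Probes cross three action patterns — constant (a-a-a-a), alternating
(a-b-a-b), all-different (a-b-c-d) — with three reward patterns — constant
(all equal), ascending, descending — giving nine category cells. Within a
cell, variants (default 8) vary the concrete reward values (constant
levels below and above the 50-point midpoint) and which options play the
roles a, b, c, d. All-different assignments are restricted to the four
rotations of the 1→2→3→4 cycle so "pattern completion" is well defined:
the continuation is always the window's first action. Canonical anchors
hold by construction and are tested: equal rewards on all-different
actions leave the Q-model exactly uniform for any parameters; ascending
rewards 20-30-70-80 put its argmax on the fourth action, descending
80-60-40-20 on the first.

Distributions are compared with the symmetric Kullback–Leibler distance
(the mean of the two directed divergences, in nats), with components
floored at 10⁻¹⁰ before the logarithms — a safety net only, since softmax
outputs are strictly positive. Cells aggregate by the arithmetic mean of
per-probe distances. Convergence labels compare the exploratory model's
distance to each explicit model: "both" when the explicit models are
within 0.05 nats of each other, "neither" when both distances exceed 1.0
nat, otherwise the nearer model; both thresholds are arguments and are
echoed with results.

## Problem sizes

The shipped test suite and acceptance script run at desk scale: a
300-participant mixture population (≈35,000 training windows), 50-epoch
training, one evaluation fold for the headline ordering, a 72-probe set,
and a 200-participant recovery study. The full five-fold pipeline at the
same sizes is exercised end-to-end at reduced dimensions (tens of
participants, small hidden layers) to keep it cheap; all sizes scale up by
argument.

## Limitations

- **Repeat dominance.** Synthetic populations built from near-greedy
  Q-learners and deterministic pattern agents repeat their previous action
  far more often than noisy human populations do. Both recurrent models
  therefore achieve high absolute accuracies, and their margin over each
  other is small; the interesting quantity is the ordering and the
  participant-level structure, not the absolute level.
- **Off-distribution probes.** Because payoffs drift by only a few points
  per trial, a 4-step window never pairs a constant action with a steep
  reward decline during training; agents that would abandon a falling arm
  do so long before a 60-point drop can accumulate. Probe stimuli with
  steeply descending rewards are therefore far outside the training
  distribution, and a model faithful to these synthetic populations
  continues the pattern there rather than switching — the probe taxonomy
  separates the explicit models sharply, but what the black box does on
  such cells reflects the population it was trained on. On noisier,
  reward-responsive populations (such as human data loaded through
  `load_real_records()`) the same cells can flip toward the
  reward-oriented model.
- **Hybrid agents are a construct.** The value-gap switching rule is the
  simplest generator of mixed strategies; it is not a fitted model of any
  empirical population.
- **Passing tests on synthetic data** show the pipeline's components are
  correct and the comparison machinery behaves as designed; they do not
  certify conclusions about any particular real dataset.
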