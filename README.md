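# banditlens

Characterising black-box models of human choice in restless bandit tasks
with explicit cognitive models.

## The problem

In a restless four-armed bandit, each arm's payoff follows a slow Gaussian
random walk (drift sd σ = 2.8 points per trial, values bounded in [1, 98]),
so a decision maker must keep re-learning which arm pays best. A
high-capacity recurrent network (single-layer LSTM, 64 hidden units) trained
on fixed-length windows of the last K = 4 (action, reward) pairs predicts
the next choice well — but it is a black box. `banditlens` implements a
pipeline that *explains* such a model by triangulating it against two
explicit cognitive models:

- the **reward-oriented model**: Q-learning with the delta rule
  `Q_{t+1}(a_t) = Q_t(a_t) + α (r_t − Q_t(a_t))`, values initialised at 50,
  and softmax choice `p_t(a) ∝ exp(β Q_t(a))`, with the group-level (α, β)
  estimated by maximum likelihood (L-BFGS-B, multi-start);
- the **reward-oblivious model**: the same recurrent architecture fed only
  the action sequence, which can capture motor/choice patterns
  (constant a–a–a–a, alternating a–b–a–b, cycling a–b–c–d) but nothing
  about outcomes.

Three lenses connect them:

1. **Held-out accuracy** under participant-wise cross-validation (argmax
   prediction, evaluated once per participant on non-overlapping windows).
2. **Trial-wise similarity**: for each trial, the fraction of participants
   on which two models agree in correctness (both right or both wrong).
3. **Experimental simulations**: hand-designed 4-step probes crossing three
   action patterns with three reward patterns (constant / ascending /
   descending); each model's fifth-choice distribution is compared by
   symmetric Kullback–Leibler distance
   `SymKL(P₁,P₂) = ½ Σₐ P₁ log(P₁/P₂) + ½ Σₐ P₂ log(P₂/P₁)`, aggregated per
   probe-category cell and labelled by which explicit model the black box
   tracks.

Because the package targets method development and validation, it ships a
first-class synthetic-agent module: heterogeneous populations of
Q-learners, deterministic pattern followers, value-gap-switching hybrids
and uniform-random agents on drifting payoff structures, with missed trials
(as in the original task's 4-second response deadline). Real data in the
same long CSV format load through `load_real_records()`.

## Worked example

```r
library(banditlens)
cfg <- bandit_config(n_participants = 90, n_folds = 3, epochs = 15,
                     batch_size = 512, variants_per_cell = 4, seed = 42)
study <- run_bandit_study(cfg, verbose = FALSE)
print(study)
```

```
Synthetic restless-bandit study
  population: 90 participants, 150 trials, mixture [q_learning=0.40, pattern=0.30, hybrid=0.20, random=0.10]
  held-out accuracy: exploratory 0.866 | reward-oblivious 0.865 | q-model 0.578
  fitted q-model: alpha=1.000 beta=0.034
  probe-cell convergence labels:
    all_different x ascending  -> reward_oblivious
    alternating   x ascending  -> reward_oblivious
    constant      x ascending  -> reward_oblivious
    ...
```

Reading the output: the exploratory (actions + rewards) network predicts
86.6% of held-out choices, edging out the reward-oblivious network (86.5%),
and both far exceed the group-level Q-learning model (57.8%) — the ordering
expected when a sizeable share of behaviour is pattern-like rather than
reward-driven. The fitted α = 1.0, β = 0.034 say the pooled population looks
fast-updating and noisy to a pure reward-learner. The probe cells show the
black box converging with the reward-oblivious model on this synthetic
population, whose choice patterns are strongly repeat-dominated (see the
methods vignette for why, and for how this differs from noisier human
populations).

Individual stages are ordinary functions returning classed objects:
`generate_payoff_structure()`, `generate_population()`, `make_windows()` /
`build_dataset()`, `split_by_participant()`, `policy_net()` (with
`predict()`, `summary()`), `qlearn()` (with `coef()`, `logLik()`,
`predict()`), `evaluate_policy()`, `accuracy_by_participant()`,
`similarity_over_time()`, `enumerate_probes()`, `sym_kl()`,
`distance_matrix()`, `classify_convergence()`.

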