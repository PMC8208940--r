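---
title: "The learned value of control: model, design, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The learned value of control: model, design, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the science it implements: the
model and its assumptions, the experiment the synthetic-data generator
emulates, the fitting machinery, and the numerical and design choices that
were genuinely open. Nothing here states an empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## The task and the phenomenon

Participants view incongruent Stroop stimuli (a color word printed in a
different color) and freely choose, trial by trial, between color naming
(CN; control-demanding) and word reading (WR; automatic). Exactly one task
is rewarded per trial, predictable from stimulus features. A two-part
Mapping Phase (160 + 160 trials, 5 points per rewarded response) trains
single-feature contingencies: first colors of interest paired with control
words, then words of interest paired with control colors. A 200-trial
Transfer Phase (10 points) presents novel feature combinations under an
XOR rule: stimuli combining two CN-mapped features (BOTH trials) are
rewarded for WR, stimuli with exactly one CN-mapped feature (EITHER) for
CN, stimuli with none (NEITHER) for WR. EITHER frequency is manipulated
between groups (0%, 20%, 50% of transfer trials); BOTH, WR CONTROL, and
NEITHER frequencies are fixed (20%, 20%, 10%), and CN CONTROL absorbs the
remainder so CN is rewarded on exactly half the transfer trials in every
group. Because a linear feature-based learner cannot represent XOR, it
overexerts control on BOTH trials ("maltransfer"), increasingly so with
EITHER exposure.

## The agent

The agent learns `LVOC(s, c; w) = Σ wᵢ fᵢ(s, c) − cost(s, c)`. The feature
basis has 81 entries: 8 color indicators, 8 word indicators, 64 color×word
conjunctions, and one global control feature; each active feature takes
the value of the control signal `c`. Weights carry independent normal
priors `N(μ_prior, τ_prior)` and are updated by exact conjugate Bayesian
linear regression with known observation-noise variance `σ_n²`; the
posterior is a full multivariate normal (mean plus dense covariance,
updated by rank-one formulas). Control is chosen by Thompson sampling on a
grid, and the chosen intensity mixes the controlled and automatic pathway
drifts of a two-boundary diffusion that produces the response and response
time. Within-trial events are simulated by an Euler–Maruyama walk.

Key parameters, units, and defaults:

- `mu_prior = -0.17`, `tau_prior = 0.11` (points; prior over weights) and
  `d_controlled = 1.32`, `d_automatic = 3.22` (1/s): the model's best fit
  to the condition-level drift rates of the behavioral study. They are
  simulation defaults here, not re-estimated from human data (which are
  not public).
- `alpha = -1`, `beta = 1/4` (implementation/reconfiguration cost shape)
  and `omega = 0.44` points/s (opportunity cost; the wage-equivalent of
  about $8/hour at 200 points per dollar).
- `sigma_n2 = 1` (observation-noise variance of the regression). The
  source model leaves this unstated; 1.0 on a 0–10 point reward scale is
  the neutral conjugate default, and it is exposed in `lvoc_params()`.
- Control grid `c ∈ {0, 0.05, …, 1}`: the drift mixture `c·d_controlled −
  (1−c)·d_automatic` only makes sense on `[0, 1]`; 21 points resolve the
  cost curvature while keeping the argmax cheap. Ties break toward the
  smaller (less effortful) `c`; `c` before the first trial is 0.
- Diffusion defaults: threshold `a = 2`, noise `s = 1`, non-decision time
  `t0 = 0.3` s, step `dt = 1` ms, deadline 3 s. The study's group-level
  threshold/noise estimates are not printed in the available text, so
  cohort simulations draw per-participant thresholds from `N(2.0, 0.3²)`
  and noise from `N(1.0, 0.1²)` (truncated away from zero) as plausible
  individual-difference distributions for a task of this type; both are
  arguments of `simulate_lvoc_cohort()` and `sim_spec()` so that fitted
  values can be substituted.

### Cost accounting

The model's stated learning target is the experienced value
`R_t − cost(s, c_t)`, with the response-time, implementation, and
reconfiguration components all included; the same cost expression also
appears inside the value being maximized at choice time. We implement the
equations as printed on both sides, and this is the default
(`cost_in_target = TRUE`). A variant (`cost_in_target = FALSE`) regresses
only `R − ω·RT` and accounts for the deterministic components exclusively
at choice time, avoiding their appearance on both sides; it is retained
behind the flag. The distinction matters behaviorally: under the
as-printed target, unrewarded control allocations carry a sharper penalty
and extinguish maltransfer on BOTH trials at a rate that preserves the
graded group effect, whereas the split variant leaves all groups
saturated near ceiling. The cost formula itself evaluates to `2·exp(α)`
at `c_t = c_{t−1} = 0`; a `baseline_subtracted` variant removes that
constant so that allocating no control costs exactly zero. The default
keeps the formula as printed.

### What the generator emulates — and what it does not

`generate_experiment()` reproduces the trial-type composition, reward
schedule, stimulus novelty constraints, counterbalanced unique-stimulus
presentation, and within-phase randomization of the study, with one
master seed per participant. The specific CN/WR assignment of features is
a seeded choice (the published stimulus table is not recoverable from the
available text); the canonical default maps colors red and blue — and the
like-named words — to CN. Matching the word assignment to the color
assignment makes every trial type's unique-stimulus count divide its
trial count exactly; a `word_split = "random"` option draws an
independent split, in which case presentation counts can differ by one.
The generator does not emulate keypress training, congruent stimuli,
breaks, fatigue, or any within-session non-stationarity of human
participants, and its diffusion responses have no inter-trial variability
in starting point or non-decision time. Passing tests therefore show that
the *model* under the study's design produces the phenomena — not that
human data would.

## Fitting machinery

**Condition-level diffusion fits.** Drift is parameterized toward the
goal-consistent response (the upper boundary is the response matching the
rewarded task), one drift per trial type, with threshold and non-decision
time shared within a group; starting point is fixed at the midpoint and
noise at 1 by the scaling convention. The likelihood uses the standard
Wiener first-passage density evaluated by the small-time/large-time
series pair with truncation chosen per evaluation from the target error
(1e-10). `ddm_fit_mle()` maximizes it by box-constrained quasi-Newton;
`ddm_fit_bayes()` samples the same parameterization by joint random-walk
Metropolis started at the MLE, with weakly informative priors (normal on
drifts, truncated normals on threshold and non-decision time), 10,000
draws with the first 5,000 discarded by default, and a split-half
potential-scale-reduction diagnostic flagged above 1.1. This deliberately
replaces a full hierarchical participant-level model: pooled
condition-level fits recover the quantities the analyses need (drift per
trial type × group and threshold per group), and the contracts are
defined on recovery behavior, not on parity with any particular
hierarchical sampler. Posterior-difference tests subtract equal-length
sample arrays elementwise in their original order and classify the 95%
highest density interval (narrowest covering interval of the sorted
sample) as containing zero, strictly negative, or strictly positive.

**Simulation-based LVOC fit.** The likelihood of observed condition-level
drift means is a product of normal densities whose means and variances
come from repeatedly simulating the whole experiment at the candidate
parameters; the variance of per-participant mean drift is divided by the
cohort size (30 by default, matching the study's sample). Degenerate
zero-variance cells (which occur when every simulated participant
saturates a condition) are floored at 1e-8 with a warning. The optimizer
is a bounded derivative-free simplex search (parameters mapped to the box
through a logistic transform), with common random numbers: every
candidate is evaluated with the same simulation seed, making the
objective deterministic given the fit seed. The original fitting used an
external Bayesian direct-search optimizer; any robust derivative-free
method with variance control serves the same role here.

**Comparator models.** The stimulus–response learner updates feature–
response associations by a Rescorla–Wagner prediction-error rule over the
16 color/word indicators and responds through the exponentiated Luce
rule (computed with max-subtraction). Its printed update in the source
carries an apparent subscript typo (the inner sum indexes the association
by the outer feature); we implement the standard prediction-error reading
in which the prediction sums `f′(s)·A_{f′,a}`. The response space is the
two tasks, matching how choices are scored in the analyses. The
win-stay-lose-shift model repeats after reward and switches otherwise; a
strictly deterministic rule has zero likelihood on any violation, so its
likelihood uses a single lapse parameter whose maximum-likelihood
estimate is the observed violation rate. Models are compared by
`BIC = k·log(n) − 2·logL`.

## Numerical choices

- Posterior updates are rank-one (Sherman–Morrison) and exploit the
  four-entry sparsity of the feature vector; the Thompson draw uses the
  marginal of the active coordinates, which is distributionally identical
  to marginalizing a full joint draw.
- Euler step 1 ms for agent simulation. Discretization biases
  first-passage times by an amount of order √dt, which is visible against
  analytic oracles at large sample sizes; oracle-equivalence tests
  therefore use 0.1–0.25 ms steps so that discretization error sits below
  Monte-Carlo error. Deadline trials are flagged and excluded by the
  analysis filters (reward-rate computations keep them).
- The first-passage density switches between small- and large-time series
  by the smaller truncation count; probabilities are floored before logs
  only through the fit's error guard (non-finite or non-positive density
  rejects the candidate step).
- Moving averages default to a trailing window (leading entries
  undefined), since the edge handling of the published smoothing is
  unstated; a centered option exists. The reward-rate denominator
  includes response time plus 1 s feedback plus 0.1 s intertrial
  interval per trial — whether the published denominator includes the
  overheads is unstated, and this choice is exposed via
  `timing_config()`.

### Problem sizes in the test suite

The suite verifies the group-level phenomena on 100 simulated 30-
participant cohorts (10 per group), fits drift on 25 pooled cohorts,
recovers diffusion parameters from 2,000 trials, recovers the LVOC
pathway drifts from summaries built with 4 experiment repetitions of 4
participants per group, runs the XOR analysis with 60 agents over 2,400
trials, and checks comparator-model recovery on 100 single-participant
cohorts per generating model. These sizes are the package's choices for
a desk-scale reproduction; the same functions scale to larger runs.

## Known limitations

- **Global-bias variant.** To let the stimulus-independent value of
  control be learned faster than feature-specific values, the source
  describes increasing the prior precision of the global weight. Under
  exact conjugate updating, higher prior precision *shrinks* the global
  weight's per-observation movement, and in our simulations the variant
  (any multiplier, and even the reverse manipulation of inflating the
  global prior variance) does not reproduce the decrease of WR CONTROL
  drift across EITHER-frequency groups that it is meant to capture. The
  reason is structural: with a full covariance posterior, transfer-phase
  learning reaches the WR CONTROL features mainly through explaining-away
  correlations acquired in the Mapping Phase, and that channel moves WR
  CONTROL drift in the opposite direction regardless of the global
  weight's precision. The corresponding acceptance check documents this
  as a failed expectation rather than weakening the test.
- With conjunction features enabled on a balanced XOR schedule, the
  agent's performance on XOR-violating trials climbs above chance as the
  conjunction weight absorbs the residual, then hovers near indifference:
  once the agent stops allocating control on those trials it also stops
  learning about them, so the asymptote sits near — not far above — the
  linear bound.
- The diffusion layer omits inter-trial variability in starting point and
  non-decision time, and drift-rate variability is not part of the
  agent's forward model (the fitting layer can include it as a fixed
  shared parameter). Collapsing bounds are out of scope.
- Human data are not available; all empirical claims in the package's
  tests are claims about the model under the study's design.
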