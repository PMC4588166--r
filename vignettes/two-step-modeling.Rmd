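---
title: "Modelling choice in the two-step task: simulation, hierarchical fitting and behavioural statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling choice in the two-step task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twostepr)
```

## The task and what the package models

In the two-step task a subject makes two choices per trial. The first-stage
choice between two fractals leads probabilistically to one of two
second-stage states: each first-stage action has a *common* destination
(probability 0.7) and an *uncommon* one (probability 0.3). The second-stage
choice between another fractal pair is rewarded with a probability that
drifts across trials, so subjects must keep re-estimating which second-stage
fractal currently pays. Because the transition structure is stable while
rewards drift, the task dissociates two learning strategies:

* **Model-free** control repeats first-stage actions that were recently
  rewarded, regardless of whether the transition that produced the reward
  was common or uncommon.
* **Model-based** control combines knowledge of the transition structure
  with second-stage values, so a reward obtained after an *uncommon*
  transition increases the value of the *other* first-stage action.

The experimental design the simulator emulates trains two groups over three
days. The *high-load* group plays alternating single-task (128-trial) and
dual-task (64-trial) blocks on every day, two blocks of each per day; on
dual-task trials a concurrent numerical Stroop judgment loads working
memory. The *low-load* group plays only single-task blocks (2 x 128 trials)
on days 1-2 and the alternating protocol on day 3. We model the concurrent
task only through a per-trial Bernoulli correctness outcome — its stimuli
and timing are out of scope.

## The hybrid learner

The package implements the standard hybrid Q-learner. With states
$s_A$ (first stage) and $s_B, s_C$ (second stage) and actions $a_A, a_B$:

* **Model-free (TD) values.** The visited pair updates as
  $Q_{TD}(s,a) \leftarrow Q_{TD}(s,a) + \alpha\,\delta$ with
  $\delta = r + \gamma \max_{a'} Q_{TD}(s',a') - Q_{TD}(s,a)$, $\gamma = 1$
  throughout, first-stage reward always 0, and terminal continuation value
  0 at the second stage. After the outcome, the second-stage prediction
  error is credited to the first-stage action via the eligibility trace:
  $Q_{TD}(s_A,a_1) \leftarrow Q_{TD}(s_A,a_1) + \alpha\lambda\,\delta_2$.
* **Model-based values.** Bellman combination of the (known) transition
  matrix with the current second-stage values,
  $Q_{MB}(s_A,a) = \sum_{s'} P(s'\mid s_A,a)\max_{a'}Q_{TD}(s',a')$,
  recomputed on every trial. Transition beliefs are fixed at the true
  matrix from the first trial: practice trials (not simulated) are assumed
  sufficient to learn it, and the simple two-alternative counting scheme
  settles there within a few trials anyway.
* **Hybrid mixture.** First-stage action values are
  $Q = w\,Q_{MB} + (1-w)\,Q_{TD}$ with $w \in [0,1]$; $w = 0$ and $w = 1$
  are the pure model-free and model-based families, implemented as fixed
  values of the same likelihood (the nesting is exact to machine
  precision, and all families coincide at the second stage).
* **Multi-day weight drift.** When fitting all days jointly the weight is
  modulated as $w_D = w\,e^{\sigma(\mathrm{Day}-2)}$. The printed formula
  can exceed 1 (e.g. $\sigma > 0$ on day 3), so the implementation clips
  $w_D$ into $[0,1]$ to keep the mixture convex. A note on the sign of
  $\sigma$: with this formula a *negative* $\sigma$ yields a *smaller*
  weight on day 3 than day 1. Statements that a negative slope indicates
  more model-based control late in training are inconsistent with the
  formula as printed; we expose the formula exactly and leave the
  interpretation to the analyst.
* **Action selection.** Softmax with lapse:
  $P(a) = \varepsilon + (1-2\varepsilon)\,
  \mathrm{softmax}(\beta Q)[a]$, computed with max-subtraction. The lapse
  compresses probabilities into $[\varepsilon, 1-\varepsilon]$ so choices
  unrelated to the value function (attention lapses, wrong buttons) do not
  distort the remaining parameters.

### Parameters, units, defaults

| parameter | meaning | range | fitting scale |
|---|---|---|---|
| $\alpha$ (optionally $\alpha^1,\alpha^2$) | learning rate | $[0,1]$ | logit |
| $\beta$ (optionally $\beta^1,\beta^2$) | inverse temperature | $\ge 0$ | log |
| $\varepsilon$ | lapse rate | $[0,0.5)$ | scaled logit |
| $w$ | model-based weight | $[0,1]$ | logit |
| $\lambda$ | eligibility trace | $[0,1]$, fixed 1 unless freed | logit |
| $\sigma$ | per-day slope on $w$ | unbounded, multi-day family only | identity |

Q-values start at 0 and are reset at day boundaries by default (walks
change across days; a flag disables the reset). Unchosen actions and
unvisited states are never updated; there is no forgetting term.

### Scoring subsets of trials

The study's analyses fit single-task and dual-task trials separately even
though the conditions alternate within a day. Passing only a condition's
rows to the likelihood treats them as a detached contiguous experience,
which misstates the agent's learning trajectory (dual blocks always occupy
the second and fourth quarters of a day). The package therefore supports a
logical `scored` column: Q-values evolve over *every* supplied trial while
only the scored choices enter the likelihood (and the iBIC choice count).
`run_pipeline()` uses this masked scoring for its per-condition fits. In
null simulations the masked route removes a source of systematic
single-vs-dual divergence; both routes remain available.

## The task simulator

Reward probabilities follow Gaussian random walks (step SD 0.025) confined
to $[0.25, 0.75]$. A pool of 15 walk *sets* — four series each, one per
second-stage fractal — is generated per cohort, and each subject draws 3
sets from the pool without replacement, one per day. (The source design
speaks of "walks" being selected per day while four fractals carry
independent probabilities; we treat the pooled unit as a set of four
series.) Boundary handling resamples the Gaussian proposal until the step
stays inside the bounds, so accepted increments remain Gaussian away from
the bounds; every raw proposal is logged, which is how the tests check the
configured step SD. Start values are uniform within the bounds (the design
does not specify them). Walks are continuous across blocks within a day and
independent across days. Practice trials and missed responses are not
simulated.

Simulation and likelihood share one compiled code path, so simulated agents
evolve exactly the Q-values the likelihood assumes.

### The synthetic cohort and what it does (not) emulate

`cohort_spec()` draws each subject's parameters from group-level Gaussians
on the fitting scale and applies condition/day offsets there. The defaults
were fixed once, before any downstream analysis, to values typical of this
task family and of the study's qualitative pattern:

* hyper-means (natural scale): $\alpha = 0.5$, $\beta = 5$,
  $\varepsilon = 0.05$, $w = 0.6$; hyper-SDs 0.5 on the fitting scale;
* a dual-task $w$ offset of $-0.5$ logits on day 1, $-0.25$ on day 2 and 0
  on day 3 in the high-load group, and 0 in the (trained) low-load group on
  day 3 — the load-by-training interaction;
* dual-task offsets of $-0.4$ on logit-$\alpha$ and $-0.3$ on
  log-$\beta$ on all days in both groups — the training-independent load
  costs on learning rate and decisiveness;
* concurrent-task accuracies of 81.9/85.5/89.5% (high-load, days 1-3) and
  83.2% (low-load, day 3).

Synthetic cohorts share the generating model with the fitted model, so
recovery results bound what fitting can achieve on real data from above:
real subjects harbour strategies outside this family (transition-learning,
heuristics, reaction-time structure, within-day drift) that no test here
exercises. Passing recovery tests shows the estimation machinery is
correct, not that the model is true.

## Hierarchical fitting

Subject parameters get a Gaussian empirical prior on the transformed scale,
estimated by expectation-maximization: the E-step computes each subject's
MAP estimate under the current prior (BFGS from the prior mean plus random
restarts — five in the first iteration, warm starts afterwards) with a
Laplace approximation $\mathcal N(\theta_i, \Sigma_i)$ around the mode
($\Sigma_i$ from a central-finite-difference Hessian, step $10^{-4}$,
eigenvalues floored at $10^{-6}$); the M-step moment-matches
$\mu = \tfrac1N\sum_i\theta_i$ and
$\sigma^2 = \tfrac1N\sum_i(\theta_i^2 + \Sigma_{i,ii}) - \mu^2$. EM stops
when every hyperparameter's relative change (with a 0.1 floor on the
denominator) falls below $10^{-3}$, or after 100 iterations. The
hyperprior starts at the transform of
$(\alpha{=}0.5, \beta{=}1, \varepsilon{=}0.05, w{=}0.5)$ with unit
variances; a free eligibility trace starts at 0.9 (1 is a boundary point
of the transform).

Model comparison uses the integrated BIC: each subject's evidence is a
log-mean-exp over the likelihood at $K = 2000$ draws from the fitted prior;
the penalty is $|M|\log|C|$ on the $-2\log$ scale, with $|C|$ counting all
*scored* choices (two per trial) and $|M|$ two hyperparameters per free
parameter. The Monte-Carlo standard error is always reported and a warning
fires above 1 nat. Group contrasts are paired t-tests on natural-scale MAP
estimates, since group results are conventionally reported on that scale;
this is a choice — the fitting scale differs — and is flagged as such.

### Known limitations we measured

Two limitations surfaced in the package's own simulations and are worth
knowing before interpreting fits of this kind:

* **Lapse hyperparameters are weakly identified at session scale.** With
  ~300 trials per subject and most subjects lapsing rarely, the marginal
  likelihood of $(\mu_\varepsilon, \sigma^2_\varepsilon)$ is nearly flat,
  and the flatness is one-sided (a subject's data can demand a lapse but
  can rarely rule one out), so the estimated group mean drifts upward and
  its variance wanders. In an identifiable regime (more lapses, longer
  sessions) the same code recovers all hyper-means to within ~0.1.
* **Paired t-tests on shrunken estimates are anticonservative.** Fitting
  two conditions separately and t-testing the per-subject MAP differences
  inherits the prior's shrinkage: with 128-trial dual blocks each
  subject's estimate collapses toward its condition's group mean, the
  paired differences have artificially small variance, and cohort-level
  estimation noise masquerades as a significant contrast in roughly half
  of null simulations. A joint hierarchical model with an explicit
  condition effect would be the principled fix; it is outside this
  package's scope, so condition contrasts here should be read with that
  caveat.

## Behavioural statistics

* **Exclusion rules** (all strict inequalities): concurrent-task accuracy
  < 70% on any day with dual-task trials; the same first-stage fractal on
  > 90% of any day's trials; P(stay | previous common and rewarded) < 0.25
  on day 1. A rule with no applicable data is skipped, not triggered.
* **Lagged logistic regression.** The response is choosing fractal A at
  stage 1; for each lag $k \in \{1,2,3\}$,
  $MF_k = \mathrm{sign(choice)}\times\mathrm{sign(reward)}$ at $t-k$ and
  $MB_k = MF_k \times \mathrm{sign(transition)}$ (common $= +1$): the two
  systems agree after common and disagree after uncommon transitions. Lags
  never cross a day or block boundary (undefined lags are coded 0). Each
  subject is fit by ridge-penalized maximum likelihood (penalty 0.01 on
  non-intercept coefficients, included because short synthetic sessions
  can separate; it vanishes relative to the likelihood as sessions grow),
  an intercept is included but not tested, and group inference is the
  two-stage random-effects summary: one-sample t-tests across subjects,
  plus summed MF/MB indices per subject.
* **Switch-stay analyses.** P(repeat first-stage choice) by previous
  transition x outcome, within condition and day; cells with fewer than 2
  pairs are missing, not 0. The one-back regression across days adds
  centred day ($\mathrm{day}-2$, matching the $\sigma$ convention) and
  day-interaction regressors residualized against their parent terms
  (Gram-Schmidt within subject), so each interaction captures only
  variance its parent leaves unexplained.
* **Concurrent-task summaries.** Accuracy among dual-task trials per
  subject and day; subjects without dual-task trials are absent, not 0%.

## Numerical and design choices worth knowing

* Problem sizes in the test-suite simulations (cohorts of 10-20 subjects,
  150-300 trial sessions, 10 replicates per recovery claim) were chosen as
  the smallest sizes at which the corresponding effects are stable; the
  walk-SD check pools over $10^5$ raw increments.
* Seeds: one master seed per cohort deterministically derives every
  subject-, day- and stage-level stream, so every simulation and fit is
  bit-reproducible; `ibic()` is bit-reproducible given (seed, K).
* Degenerate inputs: empty sessions score 0; $\beta = 0$ with
  $\varepsilon = 0$ gives the closed-form $2N\log 0.5$; zero-variance
  walks are constant; zero hyper-SD collapses a parameter across the
  cohort; day gaps and out-of-order trials are rejected.
* `glmnet`-style penalized fits were deliberately not used for the lag
  regressions: the fixed 0.01 penalty of the two-stage procedure is easier
  to state and verify with a direct Newton fit, which the tests check
  against `stats::glm` in the zero-penalty limit.
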