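---
title: "Modeling normative choice with an attribute-weighted drift diffusion model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling normative choice with an attribute-weighted drift diffusion model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(attrddm)
```

## The model

Self-control dilemmas - choosing between a selfish and a generous split of
money, or between a tasty and a healthy food - are modeled here as
evidence accumulation over weighted attributes. Each trial presents two
options described by the same attributes (dollars for self and other,
taste and health ratings, and so on). An evidence signal starts at zero
and accumulates

$$EA_t = EA_{t-1} + \sum_i w_i\,(A_{i1} - A_{i2}) + C + \varepsilon_t,
\qquad \varepsilon_t \sim N(0, \sigma),$$

until it first reaches $+B$ (choose option 1) or $-B$ (choose option 2).
The attribute weights $w_i$ express the decision maker's current goals; a
constant $C$ captures any stimulus-independent bias. Decision time plus a
fixed non-decision time gives the response time (RT), and the summed
absolute evidence $\sum_t |EA_t|$ over the decision serves as a proxy for
the aggregate neural activity the accumulation process should generate:
choices that keep the accumulator wandering near zero for a long time
produce large values, easy choices small ones.

A choice is *normative* when the chosen option has the higher unweighted
value on the normative attribute (the more generous payoff, the healthier
food), *hedonistic* otherwise; exact ties are *undefined* and excluded
from aggregates so they stay deterministic. A trial is a *conflict* trial
when the hedonic and normative attribute differences have opposite signs.

## Time discretization

The accumulation equation above is interpreted as the unit-time update of
a continuous diffusion, and simulated on an Euler grid: with step size
$\Delta t$ (`step_duration`, default 10 ms) the increment is
$d\,\Delta t + \sigma \sqrt{\Delta t}\, Z_t$, where
$d = \sum_i w_i (A_{i1}-A_{i2}) + C$ is the net drift rate. Weights and
$C$ are therefore rates per second, and $\sigma$ (fixed at 0.1) scales
with $\sqrt{s}$.

This choice matters more than it may look. If the equation is instead
simulated literally - one Normal$(0, 0.1)$ increment per step against
$B = 0.15$ - decisions terminate within a handful of steps. In that
regime the discrete walk overshoots the boundary by a non-negligible
fraction of $B$, which (a) inflates choice probabilities relative to the
first-passage law and (b) creates an artifactual asymmetry in which
boundary hits *against* the drift carry less summed evidence than hits
with the drift. That artifact reverses the characteristic no-conflict
activity pattern (below) and compresses all RT variation into tens of
milliseconds. Under the Euler reading, simulated probabilities converge
to the Wiener closed form

$$P(\text{upper}) = \frac{1}{1 + e^{-2 d B / \sigma^2}},$$

conditional RT and activity distributions become boundary-symmetric, and
decisions at the default $B = 0.15$, $\sigma = 0.1$ take on the order of
0.5-4 s - the range human subjects produce under a 4 s response deadline.
The test suite checks the simulator against the closed form on a ladder
of drifts and thresholds at a fine step (where the continuum result is
the correct reference); at coarse steps the residual overshoot bias is a
known property of Euler first-passage schemes, not a target of inference.

Paths that have not crossed a boundary by a step cap (default: the 4 s
deadline) are flagged and treated as missed responses, never silently
dropped. The accumulator starts unbiased at $EA_0 = 0$; any start bias is
expressed through $C$ only.

## The dilemma grid experiment

`build_attribute_grid()` crosses hedonic and normative attribute
differences over $[-3, +3]$ (49 cells), and `build_weight_contexts()`
supplies goal contexts: four exemplars (hedonic/normative weight pairs
0.05/0.02, 0.04/0.03, 0.03/0.04, 0.02/0.05) plus the remaining 32 points
of the $0\!-\!0.05$ factorial lattice in 0.01 steps.
`run_dilemma_experiment()` simulates each context x cell (default 10,000
decisions; $C = 0$ and zero non-decision time, neither of which affects
the aggregates) and tallies the normative-choice fraction and per-choice
mean RT and activity.

`summarize_by_conflict()` pools these into context x conflict strata.
The pooling is count-weighted over cells: normative and hedonistic
choices come from systematically different cells (a hedonistic choice
under health-favoring weights mostly happens where the taste advantage
is large and the health advantage small), and this composition is what
produces the signature patterns:

* conflict trials show fewer normative choices when the hedonic
  attribute carries the larger weight, while no-conflict trials are
  insensitive to the weights;
* in conflict trials normative choices generate *more* simulated
  activity than hedonistic ones only under hedonic-priority weights, and
  *less* under normative-priority weights;
* in no-conflict trials normative choices always generate less activity;
* every such contrast has the same sign whether computed from the
  activity proxy or from RT.

Averaging per-cell contrasts instead of pooling - or dropping cells where
one choice type is rare - removes precisely the cells that carry the
composition effect and destroys these patterns; the cell table therefore
reports per-cell contrasts (suppressed below 20 instances per choice
type) for inspection, but stratum summaries always pool. The test suite
verifies all four patterns at the exemplar weights on the full grid at
10,000 simulations per cell.

## Simulation-based fitting

There is no closed-form likelihood for trial-varying multi-attribute
drift, so `fit_ddm()` estimates one by simulation. For each distinct
stimulus, `n_sims` decisions are simulated under the candidate
parameters and turned into a joint choice x RT probability in one of two
ways:

* **histogram** (default): counts in 50 ms RT bins per boundary plus a
  censoring cell, Laplace-smoothed with pseudo-count
  $\varepsilon = 1/(n_{\text{sims}} \cdot n_{\text{bins}})$ so no
  observed datum has probability zero. The likelihood simulation uses a
  50 ms Euler step - matching the bin width, since resolving the
  simulation finer than the bins adds cost but no information.
* **kernel**: a Gaussian kernel density (bandwidth 0.1 s) over the
  simulated RTs of the matching boundary, floored at
  $1/(n_{\text{sims}} \cdot \text{deadline})$. At equal `n_sims` its
  Monte-Carlo variance is an order of magnitude below the histogram's
  (zero-count bins are what make the histogram estimator noisy), which
  is why the parameter-recovery analyses below use it.

Missed trials contribute the probability of no boundary crossing before
the deadline; a candidate non-decision time larger than an observed RT
simply sends that trial to the smoothing floor.

Sampling uses differential-evolution MCMC: $3N$ chains for $N$ free
parameters (one weight per attribute, $C$, $B$, non-decision time;
$\sigma$ stays fixed), initialized over-dispersed by uniform draws over
the prior box. Each chain proposes
$\theta' = \theta + \gamma(\theta_a - \theta_b) + U(-10^{-4}, 10^{-4})$
from two other randomly chosen chains, with
$\gamma = 2.38/\sqrt{2N}$ and $\gamma = 1$ on a random 10% of proposals
for mode jumping, Metropolis-accepted under uniform priors. Because the
likelihood estimate is stochastic, the current state's estimate is
re-drawn every iteration (`refresh = TRUE`): a chain that keeps a lucky
high estimate otherwise sticks for hundreds of iterations and ruins
convergence. Defaults follow common practice for this sampler family:
500 burn-in plus 1500 kept iterations, posterior means as point
estimates, and the Gelman-Rubin $\hat R$ (between/within-chain variance
ratio on the kept samples) as the convergence diagnostic, with
$\hat R < 1.05$ the usual bar.

Default prior bounds are weights in $[-0.01, 0.02]$ per attribute unit
per second (negative values allowed - an inequity-related attribute can
legitimately carry either sign), $C \in [-0.1, 0.1]$,
$B \in [0.05, 0.4]$, and non-decision time in $[0.1, 1.5]$ s capped at
the fastest observed response. These bracket typical fitted values for
dollar- and rating-scaled attributes with wide margins. Posterior draws
respect the box exactly; proposals outside it have zero prior mass.

## What parameter recovery can and cannot show

Recovery quality is bounded by the information in the design, not only
by the sampler. With rating-scaled food stimuli (attribute differences
in $\pm 2$), true weights of 0.001-0.006, $B = 0.15$ and a 4 s deadline,
the choice-probability logit per attribute unit is
$2 B w/\sigma^2 \approx 30 w \le 0.18$: even an ideal observer applying
logistic regression to the exact continuum choice probabilities recovers
the two weights with a truth-estimate correlation of only about 0.5 at
300 trials, because the deadline caps how large $B$ (and hence the
logit) can be while RTs remain almost uninformative about weights this
small. No sampler can beat that bound. Dollar-scaled altruistic stimuli
($0-100 against a $50/$50 default) are far more informative - attribute
differences reach $\pm 50$, so near-indifference trials pin the weights
- and the same ideal-observer analysis gives correlations above 0.9.
The package's recovery experiment therefore uses the altruistic design:
10 subjects x 300 trials (30 distinct proposals on a $5 lattice, each
presented 10 times), true weights for self and other drawn from
$[0.001, 0.006]$ with the dominant weight at least 0.0015 above the
other (mirroring the size of goal-manipulation effects on fitted
weights; with near-equal truths "ordering recovered" would be a coin
flip rather than a property of the method), plus a small fairness
weight. Food-task recovery is asserted only at the level the
information budget supports: group-level sign and ordering, not tight
per-subject correlation.

## Trial-wise neural regressors

`predict_trial_activity()` turns fitted (or known) parameters into a
per-trial prediction of accumulation activity: simulate the trial's
stimulus (default 10,000 times), keep the simulations that end in the
observed binary choice within ±250 ms of the observed RT, and average
their $\sum_t |EA_t|$. When no simulation matches, a fallback ladder
engages and is flagged per trial: widen the RT window in 250 ms
increments up to ±1 s, then match on choice alone, then mark the trial
missing. Simulated RT includes the fitted non-decision time, since it is
compared against observed RT. `build_event_table()` lays the predictions
out as onset / duration (= RT) / amplitude rows - the three-column event
format fMRI design software consumes - with optional mean-centering of
amplitudes; missing predictions are dropped with a message. Convolution
with a hemodynamic response and everything downstream is out of scope.

The 4-point response scale observed in these tasks is collapsed to its
accept/reject sign for both fitting and regressor matching (the model
has two boundaries); preference strength is kept only as metadata, and
the synthetic generator fabricates it from the net drift (sign for
direction, magnitude above the within-condition median for "Strong") as
schema plumbing, not as a behavioral model.

## Synthetic data

The generators emulate the two task families' stimulus structure so the
whole pipeline is testable without any external data:

* `generate_altruistic_trials()`: integer prize pairs in a configurable
  range against a constant default, always one party strictly above
  their default and one at or below - every trial is a genuine
  generosity/self-interest tradeoff. A derived fairness attribute
  ($|{\$}\text{Self} - {\$}\text{Other}|$ per option) is materialized as
  a column so the accumulator stays attribute-agnostic. The original
  task's probabilistic 60/40 payout affects incentives, not the decision
  process, and is not modeled.
* `generate_food_trials()`: integer taste/health ratings relative to a
  neutral reference food at (0, 0), drawn by sign quadrant with
  configurable mixing (or uniformly, which also produces degenerate
  zero-difference trials).
* `generate_behavior()`: runs the accumulator once per trial under
  known, per-condition parameters; RTs beyond the deadline (or paths
  that never cross) become missed trials with all responses blank.
* `generate_cohort()`: a multi-subject food-task cohort with a truth
  table of generating parameters for recovery scoring.

What the generators do *not* emulate: rating noise, session and order
effects, attribute correlations in real food databases, non-stationary
weights within a condition, and contaminant RTs (fast guesses, lapses).
Passing tests therefore demonstrate internal consistency of model,
fitter and regressor machinery - not that real participants obey the
model.

## Problem sizes and numerical choices

The test suite runs the dilemma experiment at the four exemplar contexts
x 49 cells x 10,000 simulations; the closed-form comparison on a 5 x 5
drift x threshold ladder at 10,000 paths per cell with a 2 ms step; the
full-scale convergence fit (3N chains, 500 + 1500 iterations, 500-sim
histogram likelihood) on one 150-trial subject; and the altruistic
recovery experiment at reduced sampler settings (12 chains, 150 + 300
iterations, 200-sim kernel likelihood, 0.1 s likelihood step). Unit
tests use smaller sizes chosen so each check's Monte-Carlo error is well
below the effect it asserts, with tolerances stated as multiples of the
binomial standard error wherever a probability is compared.

Numerical conventions: the boundary test is inclusive
($|EA_t| \ge B$ triggers at the first crossing); the activity proxy sums
$|EA|$ over accumulation steps only (non-decision time contributes
nothing) and scales by $\Delta t$ so its value is step-size invariant;
normal deviates in the compiled simulator come from a Marsaglia-Tsang
ziggurat driven by R's uniform generator, so `set.seed()` makes every
simulation, fit and prediction bit-reproducible.

## Known limitations

* Point predictions at coarse Euler steps inherit overshoot bias; users
  who need tight agreement with continuum first-passage quantities
  should lower `step_duration` and pay the linear cost.
* The simulated likelihood is a noisy estimator; the sampler targets a
  correspondingly smoothed posterior. Posterior widths at the default
  settings are honest about this only up to that smoothing.
* Per-subject, per-condition fitting only - no hierarchical pooling, no
  collapsing bounds, no alternative accumulator variants, and no model
  comparison machinery.
* Weight recovery from rating-scaled (±2) stimuli is information-limited
  at realistic trial counts, as quantified above; design conclusions
  about such tasks should rest on group-level contrasts.
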