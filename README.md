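# attrddm

Attribute-weighted drift diffusion modeling of normative choice.

## The problem

When people face self-control dilemmas - keep the money or share it, eat
the sundae or the apple - their choices trade off a *hedonic* attribute
(payoff to self, tastiness) against a *normative* one (payoff to the
other person, healthiness). `attrddm` implements an evidence-accumulation
account of such decisions for researchers in decision neuroscience: the
model simultaneously predicts what is chosen, how long the decision
takes, and how much aggregate neural activity the selection process
should generate - the quantity used as a trial-wise fMRI regressor in
model-based analyses of regions such as the dorsolateral prefrontal
cortex.

## The model

Evidence accumulates from zero as

    EA_t = EA_{t-1} + sum_i w_i (A_i1 - A_i2) + C + eps_t,   eps_t ~ N(0, sigma)

until it reaches +B (choose option 1) or -B (choose option 2). The `w_i`
are goal-dependent attribute weights, `C` a constant bias, and RT is the
crossing time plus a non-decision time `ndt`. Simulated neural activity
is `sum_t |EA_t|` over the decision. The update is treated as the
unit-time step of a continuous diffusion and simulated on a configurable
Euler grid (10 ms by default, with sigma = 0.1, B = 0.15). Choices are
*normative* when the chosen option is higher on the normative attribute;
trials are *conflict* trials when the two attribute differences have
opposite signs.

The package provides, as tidy data-frame-in / tibble-out verbs:

* `simulate_ddm()`, `net_drift()`, `classify_normative()`,
  `classify_conflict()` - the accumulator core;
* `build_attribute_grid()`, `build_weight_contexts()`,
  `run_dilemma_experiment()`, `summarize_by_conflict()` - the simulation
  study over attribute-difference grids and goal-weight contexts, with
  `autoplot()` heat maps;
* `approximate_log_likelihood()`, `fit_ddm()`, `gelman_rubin()` -
  simulation-based Bayesian estimation by differential-evolution MCMC
  (`tidy()`, `glance()`, `autoplot()` methods included);
* `predict_trial_activity()`, `build_event_table()`,
  `write_event_file()` - trial-wise model-predicted activity regressors
  in three-column fMRI event format;
* `generate_altruistic_trials()`, `generate_food_trials()`,
  `generate_behavior()`, `generate_cohort()` - synthetic dictator-game
  and dietary-choice datasets with known generating parameters;
* `read_trials()` / `write_trials()` - a validated CSV trial schema
  shared by both tasks.

## Worked example

Simulate a dieter facing taste/health dilemmas under taste-prioritizing
weights, then summarize by conflict status:

```r
library(attrddm)
set.seed(1)

cells <- run_dilemma_experiment(
  build_attribute_grid(-3:3),            # 49 attribute-difference cells
  build_weight_contexts()[1:4, ],        # the four exemplar goal contexts
  n_sims = 10000
)
summarize_by_conflict(cells) |>
  dplyr::select(context_label, conflict_status, p_normative,
                delta_neural, delta_rt) |>
  print(n = 8)
```

```
#> # A tibble: 8 x 5
#>   context_label          conflict_status p_normative delta_neural delta_rt
#>   <chr>                  <fct>                 <dbl>        <dbl>    <dbl>
#> 1 w_hed=0.02,w_norm=0.05 conflict              0.806     -0.00996  -0.205
#> 2 w_hed=0.02,w_norm=0.05 no_conflict           0.974     -0.0130   -0.271
#> 3 w_hed=0.03,w_norm=0.04 conflict              0.620     -0.00302  -0.0580
#> 4 w_hed=0.03,w_norm=0.04 no_conflict           0.975     -0.0117   -0.236
#> 5 w_hed=0.04,w_norm=0.03 conflict              0.382      0.00298   0.0624
#> 6 w_hed=0.04,w_norm=0.03 no_conflict           0.976     -0.0121   -0.249
#> 7 w_hed=0.05,w_norm=0.02 conflict              0.192      0.00941   0.198
#> 8 w_hed=0.05,w_norm=0.02 no_conflict           0.974     -0.0140   -0.274
```

Read across the rows: healthy (normative) choices become rare in
conflict trials exactly when taste outweighs health (`p_normative` 0.19
vs 0.81), while no-conflict trials are insensitive to the goal weights
(~0.97 everywhere). The activity contrast `delta_neural` (normative
minus hedonistic choices, in evidence-seconds) is *positive* in conflict
trials only under taste-priority weights - choosing healthily against
one's goals is what drives the accumulator longest - and negative
everywhere else; the RT contrast `delta_rt` (seconds) agrees in sign
with it in every stratum.

Fitting and regressor construction on synthetic data:

```r
set.seed(2)
truth  <- ddm_params(c(taste = 0.004, health = 0.002), ndt = 0.4)
trials <- generate_behavior(generate_food_trials(150), truth)
fit    <- fit_ddm(trials, n_burn = 500, n_keep = 1500, n_sims = 500)
glance(fit)                      # acceptance rate, max Gelman-Rubin R-hat
tidy(fit)                        # posterior means, CIs, per-parameter R-hat

obs   <- dplyr::filter(trials, !missed)
preds <- predict_trial_activity(obs, params_from_fit(fit), n_sims = 10000)
build_event_table(preds, obs)    # onset / duration / amplitude rows
```

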