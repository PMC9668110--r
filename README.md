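# normadapt

Computational modeling of fairness-norm adaptation in a conditioning
Ultimatum Game.

## The problem

In the Ultimatum Game a Proposer splits an endowment (here 20 tokens) and a
Responder accepts the split — both sides are paid — or rejects it, leaving
both with nothing. A Responder's rejections enforce an internal *fairness
norm*: the offer they believe they should receive. In the conditioning
variant of the task, a Responder plays 60 one-shot rounds against different
Proposers in three 20-trial blocks: a baseline block of medium offers
(Gaussian, mean 8, SD 1.5 tokens), a conditioning block of low offers (mean
4, SD 1.5), and a post-conditioning block drawn from the same medium
distribution as baseline. If exposure to low offers shifts the internal
norm downward, rejection rates for identical medium offers should be lower
after conditioning than before.

`normadapt` is for researchers who want to simulate this paradigm, fit
norm-learning models to trial-level choice data, and run the associated
model-free statistics — or to validate that whole pipeline by parameter and
model recovery on synthetic cohorts.

## The models

Choice utility is Fehr–Schmidt inequity aversion around the current norm
*x*:

    U_t(s_t) = s_t − α · max(x_t − s_t, 0) − β · max(s_t − x_t, 0)

with envy α (penalty for offers below the norm) and guilt β (offers above
it). Acceptance follows a softmax with inverse temperature γ:

    P_t(accept) = 1 / (1 + exp(−γ · U_t))

Six candidate models differ only in how the norm evolves:

| model      | norm update                                    | free parameters |
|------------|------------------------------------------------|-----------------|
| `FS_fixed` | static norm, 10 tokens (equal split)           | α, β, γ         |
| `FS_free`  | static norm, estimated                         | α, β, γ, x₀     |
| `BO_fixed` | Bayesian observer, prior mean 10               | α, β, γ         |
| `BO_free`  | Bayesian observer, prior mean estimated        | α, β, γ, μ̂₀    |
| `RW_fixed` | Rescorla–Wagner, x₀ = 10                       | α, β, γ, ε      |
| `RW_free`  | Rescorla–Wagner, x₀ estimated                  | α, β, γ, ε, x₀  |

The Rescorla–Wagner rule moves the norm by a fraction ε of each
norm-prediction error, `x_t = x_{t−1} + ε (s_t − x_{t−1})`. The Bayesian
observer treats offers as draws from a Gaussian with unknown mean and
variance under a conjugate Normal–Inverse-χ² prior (k₀ = 4, ν₀ = 10,
σ̂₀² = 4) and uses the posterior mean as the norm. Each model is fitted per
participant by multi-start bounded maximum likelihood over the 60 choices;
models are compared by BIC and AIC summed across participants (lowest sum
wins).

The model-free analyses are the paired baseline/post rejection-rate
contrast (with Cohen's d = |t|/√n), per-offer-size contrasts corrected by
the Benjamini–Hochberg step-up procedure, a 5-trial sliding-window
rejection curve, a mixed-effects logistic regression of rejection on offer
size, and the emotion-rating contrast.

## Worked example

```r
library(normadapt)

# a synthetic cohort of 12 responders under the winning learning model
cohort <- simulate_cohort(cohort_spec(model_id = "RW_fixed",
                                      n_participants = 12), seed = 42)

# norm adaptation: baseline vs post-conditioning rejection rates
block_contrast(cohort$trials)
#> <ug_paired> t(11) = -2.85, p = 0.01579, mean diff = -11.25 (SEM 3.95), d = 0.82

# fit all six candidate models and compare them by summed BIC/AIC
fits <- fit_cohort(cohort$trials, config = optimizer_config(seed = 1))
compare_models(fits)
#> <ug_comparison> winner (BIC): RW_fixed
#> # A tibble: 6 × 5
#>   model_id sum_bic sum_aic n_participants n_best_bic
#>   <chr>      <dbl>   <dbl>          <int>      <int>
#> 1 RW_fixed    283.    183.             12          9
#> 2 RW_free     319.    194.             12          0
#> 3 BO_fixed    542.    466.             12          1
#> 4 BO_free     555.    455.             12          1
#> 5 FS_fixed    596.    521.             12          0
#> 6 FS_free     634.    533.             12          1

# how well do the fitted learning rates track the truth?
parameter_recovery(cohort$params, fits)
#> # A tibble: 4 × 5
#>   param        bias   rmse rank_cor     n
#>   <chr>       <dbl>  <dbl>    <dbl> <int>
#> 1 alpha    0.121    0.653     0.979    12
#> 2 beta     0.254    1.01      0.281    12
#> 3 gamma    3.98     5.34      0.631    12
#> 4 epsilon -0.000789 0.0248    0.993    12
```

Reading the output: the cohort's mean rejection rate dropped by about 11
percentage points from baseline to post-conditioning (paired t(11) = −2.85,
effect size d = 0.82) — the behavioral signature of norm adaptation. The
generating model `RW_fixed` wins the summed-BIC comparison and is the
per-participant best model for 9 of 12 responders, and the learning rate ε
is recovered almost perfectly (rank correlation 0.99); the temperature γ is
the least identifiable parameter, as expected when choices are nearly
deterministic.

`run_pipeline(run_config(...))` chains
simulate → fit → compare → behavioral statistics into one seeded,
reproducible call, and `read_trial_log()` ingests real trial-level CSV logs
(`accept`/`reject` or keyboard codes `1`/`2`) into the same analyses.
Plot helpers (`plot_sliding_rejection()`, `plot_block_rates()`,
`plot_rejection_by_offer()`, `autoplot()` on comparison and recovery
objects) cover the standard figures.

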