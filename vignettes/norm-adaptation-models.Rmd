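---
title: "Norm-learning models of responder behavior: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Norm-learning models of responder behavior: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models implemented in `normadapt`, the
assumptions behind them, the numerical choices made where the design was
genuinely open, and what the synthetic-data generator does and does not
emulate.

## The task and its parameters

The conditioning Ultimatum Game presents a Responder with 60 one-shot
offers out of a 20-token endowment, in three blocks:

* **baseline** (trials 1–20): offers from a Gaussian with mean 8, SD 1.5
  tokens;
* **conditioning** (trials 21–40): mean 4, SD 1.5;
* **post-conditioning** (trials 41–60): mean 8, SD 1.5 again.

Because the baseline and post-conditioning blocks share a distribution,
any drop in rejection rates between them isolates a change in the
Responder's internal standard rather than a change in the offers. An
emotion-rating prompt (1–9 scale) follows each offer independently with
probability 0.67. (Descriptions of the paradigm alternately give 67% and
60% for the prompt rate; we default to 0.67 and expose
`rating_probability` as a `task_config()` field.)

Offers are real Gaussian draws discretized to integer tokens. The
discretization is round-half-away-from-zero — symmetric around the block
means, unlike R's default round-half-to-even — followed by clipping into
`[offer_min, offer_max]` (defaults 0 and the endowment). With SD 1.5 and
means of 4 and 8 tokens the clip boundaries are 2.7+ SDs away, so rounding
and clipping shift the block means by well under 0.01 tokens; the
large-sample mean checks in the test suite use a 0.05-token tolerance
purely for Monte-Carlo noise. Rating prompts are independent
Bernoulli draws per trial rather than a fixed quota, matching a prompt
*rate* rather than an exact count. Proposer identity is not modeled: each
trial index stands in for a distinct anonymous Proposer.

## Utility, choice, and the six norm processes

All models share the inequity-aversion utility around the current norm
$x_t$:

$$U_t(s_t) = s_t - \alpha \max(x_t - s_t, 0) - \beta \max(s_t - x_t, 0)$$

and a softmax (logistic) choice rule $P(\text{accept}) =
\text{logit}^{-1}(\gamma U_t)$. The two penalty terms cannot be active
simultaneously. Since the modified static-norm utility and the original
inequity-aversion equation are algebraically identical, one function
(`fs_utility()`) serves both.

The models differ only in the norm process:

* **FS** — the norm is constant (10 tokens, the equal split, for
  `FS_fixed`; estimated for `FS_free`).
* **BO** — a Bayesian observer treats offers as draws from a Gaussian with
  unknown mean and variance under a conjugate Normal–Inverse-χ² prior,
  hyperparameters $k_0 = 4$, $\nu_0 = 10$, $\hat\sigma^2_0 = 4$, and
  $\hat\mu_0 = 10$ (or estimated). After each offer, $k$ and $\nu$
  increment by one, the mean moves toward the offer with weight $1/k_t$,
  and $\nu_t \hat\sigma^2_t = \nu_{t-1}\hat\sigma^2_{t-1} +
  (k_{t-1}/k_t)(s_t - \hat\mu_{t-1})^2$. The norm used at trial $t$ is the
  *pre-update* posterior mean, so only the mean recursion affects the
  likelihood; the variance recursion is implemented and tested but does not
  enter choice.
* **RW** — a delta rule, $x_t = x_{t-1} + \varepsilon (s_t - x_{t-1})$,
  with learning rate $\varepsilon \in [0, 1]$.

Two modeling conventions worth stating explicitly: the norm updates on
*every* trial, after the choice, and depends only on the offer — rejecting
an offer does not stop it from shaping the norm; and the `_free` variants
nest their `_fixed` counterparts exactly at an initial norm of 10, an
identity the test suite asserts.

### Parameter bounds

Envy and guilt lie in $[0, 10]$, the learning rate in $[0, 1]$, the
initial norm in $[0, 20]$. The inverse temperature defaults to $[0, 10]$:
descriptions of the choice rule sometimes state $\gamma \in [0, 1]$, but
fitted temperatures well above 1 are routinely reported (sample mean 1.78,
SD 1.58 in the population this package emulates), which is impossible
under a unit bound. The upper bound is therefore a configurable
`gamma_max` defaulting to 10. Guilt is kept as a free parameter even
though offers above the norm are rare early in the task; its bounds match
the envy bounds.

## Likelihood and optimization

The per-participant objective is the negative log-likelihood of the 60
choices, $-\sum_t \log P(\text{choice}_t)$, with log-probabilities floored
at $\log(10^{-12})$ so the objective stays finite at saturated choices —
standard likelihood hygiene that changes nothing for interior optima.

No optimizer is canonical for this family, so fitting uses bounded
L-BFGS-B from multiple starts: the midpoint of every bound plus 10 uniform
draws within bounds (seed-controlled; the count is an `optimizer_config()`
field). The best NLL wins; ties break to the first-found. Two details
matter:

* **Nesting.** `fit_cohort()` fits each `_fixed` variant first and adds
  its solution (with the norm at 10) as an extra start for the `_free`
  variant, so the nested model can never score a worse likelihood —
  asserted to 1e−6 in the tests. The midpoint start (the norm bounds'
  midpoint is exactly 10) provides the same guarantee for standalone
  `fit_participant()` calls in the typical case.
* **Degenerate data.** A flat likelihood (e.g., choices at chance, best
  fit $\gamma = 0$) is a valid outcome: the fit reports a `converged` flag
  rather than raising. An L-BFGS-B failure at a start point falls back to
  scoring that start, never aborts the fit.

`grid_search()` provides a brute-force check: NLL evaluated at 11 points
per free parameter (up to $11^5$ nodes for `RW_free`), vectorized over the
inequity/temperature axes for each candidate norm trajectory. The test
suite requires the optimizer to weakly dominate the grid on every model
and synthetic participant tried.

BIC uses the number of choice trials (60) as the sample size per
participant: $\text{BIC} = k \ln n - 2\ell$, $\text{AIC} = 2k - 2\ell$.
Model selection sums both criteria over participants and takes the argmin;
when BIC and AIC disagree the disagreement is surfaced (`agreement =
FALSE`) with BIC treated as primary. We deliberately do not implement
random-effects Bayesian model selection or exceedance probabilities —
summed scores mirror the analysis this package reproduces; a
per-participant winner count is included as supplementary output.

## The synthetic-data generator

No trial-level data from the original study are publicly deposited, so
every downstream stage is exercised on synthetic cohorts. The generator's
defaults emulate the study conditions: 30 responders, 60 trials in
20/20/20 blocks, and per-participant parameters drawn from independent
truncated Gaussians centered on the reported sample moments — envy
2.58 (SD 2.53), guilt 0.17 (SD 0.32), temperature 1.78 (SD 1.58), learning
rate 0.16 (SD 0.28) — truncated to each parameter's bounds. Only sample
moments are reported for the fitted population, so the truncated Gaussian
is a modeling choice, not an estimated population model. Each participant
receives an independently sampled schedule, matching a design where offers
are drawn per participant rather than fixed as a list. When the initial
norm is free it is sampled around 10 (SD 3), a weakly informative choice
centered on the equal split.

Ratings have no reported generative model; the synthetic rating rule is
linear in offer size (intercept 1, slope 0.6 per token, Gaussian noise
SD 1, rounded and clipped to 1–9) and exists solely to exercise the rating
analyses. Passing tests on these cohorts show the machinery is correct and
the estimator identifiable under realistic parameter ranges; they do not
show that children's ratings, reaction times, age effects, or any
violation of the softmax-choice assumption are captured — none of those
are modeled.

A qualitative invariant ties the generator to the phenomenon: cohorts
simulated from `RW_fixed` at the default sampler show, on average across
replicate cohorts, lower post-conditioning than baseline rejection — the
conditioning signature.

## Model-free statistics

* `block_contrast()` / `paired_contrast()`: classical paired t, two-tailed,
  sign convention post − pre (decreases are negative), effect size
  $d = |t|/\sqrt{n}$ reported as a magnitude with a noncentral-t 95% CI.
  When the difference variance is exactly zero, $t$ is reported as 0 (all
  differences zero) or flagged undefined rather than raised.
* `offer_size_contrasts()`: one paired contrast per offer size present in
  both blocks for a participant; participants missing a size in either
  block are excluded from that size's contrast (the analysis is silent on
  missing cells, so inclusion is per-size complete-case).
* `bh_correct()`: the Benjamini–Hochberg step-up procedure implemented as
  its five textbook steps (ascending sort, ranks, critical values
  $(i/m)Q$, cutoff = largest p below its critical value, significance =
  all p at or below the cutoff), default $Q = 0.05$; cross-checked against
  `stats::p.adjust(method = "BH")` in the tests. No other
  multiple-comparison procedure is offered.
* `sliding_rejection()`: trailing 5-trial windows (the window ending at
  trial $t$), per participant, then averaged; the curve for a 60-trial
  session has 56 points.
* `offer_size_regression()`: rejection is the positive class and the
  predictor is coded as tokens below the endowment midpoint
  (`endowment/2 − offer`), so the coefficient is the log-odds increase in
  rejection per token *removed* from the offer and the odds ratio is
  above 1 for offer-sensitive responders. The default random-effects
  structure is a per-participant random intercept and slope
  (`lme4::glmer`); the original analysis describes its random slopes
  ambiguously, so this default is our own stated choice. If the mixed fit
  fails to converge the function falls back, with a logged warning, to a
  pooled logistic regression with participant-clustered (sandwich)
  standard errors.
* `rating_contrast()`: the same paired machinery applied to
  per-participant block-mean ratings.

One arithmetic note: $d = |t|/\sqrt{n}$ reproduces some published paired
effect sizes exactly (e.g., $3.89/\sqrt{30} = 0.71$, $2.44/\sqrt{30} =
0.45$) but not all printed values in this literature; where a printed d
disagrees with its own printed t, this package follows the formula.

## Problem sizes and reproducibility

All randomness flows through explicit integer seeds
(`withr::with_seed`), so every simulation, fit, and pipeline run is a pure
function of its configuration and seed; `run_pipeline()` stamps its
outputs with a fingerprint of the configuration. The validation suite runs
at the study's scale where the claim depends on it — parameter/model
recovery uses 10 replicate cohorts of 30 responders × 60 trials with all
six candidate models — and at reduced scale (4–12 participants, fewer
restarts) for structural checks like determinism, nesting, and output
formats, where problem size carries no evidential weight.

## Known limitations

* The temperature $\gamma$ is weakly identified when choices are nearly
  deterministic (the likelihood flattens as $\gamma \to$ its bound); its
  recovery is visibly worse than $\varepsilon$ or $\alpha$ in the worked
  examples. This mirrors the usual behavior of softmax temperatures.
* Guilt $\beta$ is poorly constrained by this design — offers rarely
  exceed the norm before conditioning lowers it — so $\beta$ recovery is
  weak by construction.
* Hierarchical (group-level) estimation, exceedance probabilities,
  proposer behavior, reaction times, and developmental covariates are out
  of scope.
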