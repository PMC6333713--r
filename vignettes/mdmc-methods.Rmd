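---
title: "The multimodal diffusion model for conflict tasks: model, simulator and estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The multimodal diffusion model for conflict tasks: model, simulator and estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdmc)
```

## The model

In a Simon-type conflict task the participant responds to a non-spatial
stimulus attribute (here: letter identity) while task-irrelevant location
information interferes. This package implements a multimodal extension of
the diffusion model for conflict tasks in which *several* task-irrelevant
modalities (e.g. visual position plus tactile or auditory position)
contribute automatic activation simultaneously.

The reaction time decomposes as RT = D + R: a decision time D from a
diffusion race to one of two symmetric boundaries, plus a residual
(non-decision) time R. The decision process is a superposition

$$X(t) = X_c(t) + \sum_m X_{a,m}(t),$$

of a controlled process with constant drift $\mu_C$ and one automatic
process per task-irrelevant modality $m$. The expected time course of an
automatic process is a pulse shaped like a rescaled Gamma density,

$$E[X_a(t)] = A\, e^{-t/\tau} \left[\frac{t\,e}{(a-1)\tau}\right]^{a-1},$$

normalised so its maximum is exactly $A$, attained at $t = (a-1)\tau$. Its
time derivative is the automatic drift contribution; it is positive before
the pulse peak and negative after it, which is what produces the classic
negative-going delta functions: the congruency effect is largest for fast
responses and shrinks (or reverses) for slow ones. The congruency of each
modality enters only as the sign of its pulse: $+A$ (congruent), $-A$
(incongruent) or absent (neutral). The shape $a$ is a structural constant
fixed at 2 throughout; it is kept as an explicit field of
`automatic_spec()` to make the Gamma family visible, but it is never a free
parameter.

The trial-to-trial starting point is drawn from a symmetric
Beta$(\alpha,\alpha)$ distribution rescaled to $(-b, b)$; $\alpha$ is a
free parameter. The residual time is Normal$(\mu_R, \sigma_R)$. The
FN-MDMC variant ("faster neutral") adds one parameter, $\mu_{RN}$: the
residual mean used when the *visual* modality's label is neutral, capturing
the retinal speed advantage of foveally presented (central) stimuli. That
is the only difference between the two variants, so MDMC (9 free
parameters with two modalities) is nested in FN-MDMC (10).

## Simulator

`simulate_decision()` integrates the superimposed process with an
Euler-Maruyama scheme,

$$X(t+\Delta t) = X(t) + \mu(t)\,\Delta t + \sigma \sqrt{\Delta t}\, Z,$$

with $\mu(t) = \mu_C + \sum_m \mu_{a,m}(t)$, defaults $\Delta t = 1$ ms and
$\sigma = 4$, and absorption at $\pm b$. Numerical choices worth knowing:

* **Noise enters once, at the level of the superimposed process.** The
  per-process formulation with separate diffusion constants is not
  independently recoverable from aggregate behaviour, so a single constant
  $\sigma$ drives the summed process.
* **The automatic drift has a $1/t$ factor**, so the first Euler step
  evaluates the drift at $t = \Delta t$ rather than 0; the pulse itself
  vanishes at 0, and with $\Delta t = 1$ ms the singular point is never on
  the grid.
* **Censoring.** Trials not absorbed within 5000 ms are flagged censored
  and excluded from summaries; at realistic parameter values the censoring
  rate is below $10^{-4}$ (this is asserted in the test suite).
* **Residual times** are truncated-normal by redraw (non-positive draws are
  redrawn). At realistic scales ($\mu_R/\sigma_R \approx 9$) the truncation
  probability is $\sim 10^{-21}$, so the bias is purely formal.
* **Discretisation bias.** An Euler scheme only detects boundary crossings
  on the grid, which biases accuracy upward and first-passage times upward
  (the process can cross and return within a step). At $\Delta t = 1$ ms,
  $\sigma = 4$ and the published visual-tactile parameters the bias is
  about +0.4% on accuracy and +5 ms on mean decision time relative to the
  continuous-time Wiener closed forms. This is a property of the method of
  record, not a bug; model fitting is internally consistent because
  observed data and predictions face the same scheme. When the test suite
  checks the simulator against the continuous-time closed forms
  ($P(\text{correct}) = 1/(1+e^{-2\mu_C b/\sigma^2})$ and
  $E[D] = (b/\mu_C)\tanh(\mu_C b/\sigma^2)$) it therefore runs the scheme
  at $\Delta t = 0.01$ ms, where the residual bias is inside three
  Monte-Carlo standard errors at $n = 10^5$ trials.
* **Reproducibility.** One root seed; each condition (and each participant
  in `generate_dataset()`) gets a deterministically derived sub-stream, so
  changing one condition's trial count does not reshuffle the others.

## Distributional summaries

All summary conventions are pinned explicitly because several are
ambiguous in common usage:

* RT analysis window 150-1200 ms, **closed** interval (only strictly
  outside values are discarded), applied after dropping censored trials.
* Quantiles by linear interpolation between order statistics with plotting
  position $(k-1)/(n-1)$ (`stats::quantile()` type 7).
* CAFs sort all trials (correct and error) by RT and split them into five
  contiguous bins as equal as integer division allows, **earlier bins
  taking the remainder**; RT ties keep stable input order.
* Delta functions plot incongruent-minus-congruent quantile differences
  against the **mean** of the two quantiles.
* Marginal CDFs (one modality's level, averaged over the other modality)
  are computed **per condition and then averaged pointwise**, not pooled —
  the convention of the empirical figure captions. Fitting, in contrast,
  pools trials over participants, because the models are fitted to
  aggregated data.

## The fitting objective

Each condition contributes ten proportions to the objective: five CDF
slots and five CAF slots. The exact mapping from "five CDF quantiles and
five CAF bins" to a proportion vector is not uniquely determined in the
literature, so the package pins one convention: the CDF slots are
the masses of correct responses in the inter-quantile bins
$(-\infty, q_{.1}], (q_{.1}, q_{.3}], \ldots, (q_{.7}, q_{.9}]$ of the
observed correct-RT quantiles, and the CAF slots are the error masses in
the observed RT quintile bins, all relative to the condition's total trial
count. Predictions are scored **into the observed edges**, so the observed
vector is essentially $(0.1, 0.2, 0.2, 0.2, 0.2)\times$ accuracy plus the
per-bin error masses, and all distribution-shape information enters
through the predicted vector. Scoring a dataset against its own edges
reproduces its own proportions exactly, a property the tests assert.

The discrepancy is

$$G^2 = 2 \sum_c N_c \sum_{i=1}^{10} \left| p_{ci} \log\frac{p_{ci}}{\pi_{ci}} \right|,$$

implemented with the absolute value as printed in the source literature
(each term is non-negative, unlike the classical signed form, which is
available via `classical = TRUE`). Predicted proportions are floored at
$10^{-5}$ before the log. Model comparison uses
$BIC = G^2 + f \log \Sigma n_i$; the default $\Sigma n_i$ is the number of
trials entering the fit, with a `bic_n = "table1"` mode that uses 270
(participants $\times$ conditions), the value implied by the published
$BIC - G^2$ gaps.

## Optimisation

The objective is stochastic: predictions are Monte-Carlo simulations
(50,000 trials per condition per evaluation at the published scale).
`mdmc()` uses common random numbers — one simulation seed fixed per fit,
with per-condition sub-streams — so the surface seen by the optimiser is
deterministic, and minimises with a multi-start Nelder-Mead simplex.
Initial vectors are drawn uniformly from documented ranges bracketing
published estimates ($\mu_C \in [0.2, 1.2]$, $b \in [30, 100]$,
$\tau \in [10, 120]$, $A \in [1, 40]$, $\mu_R, \mu_{RN} \in [200, 450]$,
$\sigma_R \in [10, 80]$, $\alpha \in [1, 6]$); a wider hard validity box
is enforced by penalty. Three properties of this surface shaped the
optimiser design:

* **The surface is a staircase.** Predicted proportions are binned
  Monte-Carlo counts, so the objective is piecewise constant in the
  parameters with step width shrinking as `1/n_sim`. Once a simplex
  contracts below the local step width it stops moving regardless of how
  far it is from the optimum. The remedies are *restarted* simplex rounds
  (each round rebuilds the initial simplex at a fresh scale) and finishing
  on the finest-grained surface available (the full `n_sim`).
* **$\mu_C$ and $b$ trade off strongly**: their ratio sets the mean
  decision time and their product the hitting probability, producing a
  long curved valley in the raw parameterisation. The simplex therefore
  works in a transformed space — logarithms for the scale parameters
  ($\sigma_R$, $\alpha$, $\tau$) and the rotation
  $(\mu_C, b) \to (\log b/\mu_C,\ \log b\,\mu_C)$ — in which the valley is
  straight and axis-aligned. Results are reported in natural units.
* **Cost scales linearly with `n_sim`** while the staircase granularity
  only improves as its inverse, so `mdmc()` supports a multi-fidelity
  ladder (`screen_n_sim`): all starts are screened and polished at a
  reduced simulation size, and the winner is refined, and its final
  $G^2$ evaluated, at the full `n_sim`. The parameter-recovery checks in
  the test suite use this schedule (screen at 4,000, finish at 20,000
  simulated trials per condition).

## Synthetic data

`generate_dataset()` emulates the factorial design of the source
experiments: 3 visual positions $\times$ 3 secondary-modality positions
$\times$ 2 letters = 18 trial types, 5 repetitions per block shuffled
within block, 6 blocks, 30 participants; each participant sees each of the
nine congruency conditions 60 times (540 trials). The letter-response
mapping alternates across participants. All participants share one
parameter set, matching the aggregated-data fitting approach; an optional
lognormal jitter on $\mu_R$ exists for robustness experiments and is off
by default. The generator does **not** emulate the live experiment's
response deadline and feedback displays, letter confusability, or any
perceptual encoding differences between modalities — so passing recovery
tests show that the estimator works on data that satisfy the model's
assumptions, not that the model is true of real participants.

## Problem sizes used in the checks

The shipped checks run at deliberately reduced scale, chosen to keep each
check informative at desk-scale cost: parameter recovery generates 2,000
trials per condition and fits with 20,000 simulated trials per condition
and 5 starts (published fits used 50,000 and more starts); the
closed-form Wiener checks use $10^5$ trials; qualitative-signature checks
(delta function direction, CAF fast-bin ordering, congruency ordering of
mean RT) use 50,000 trials per condition. The permutation machinery
defaults to the published 1,000 simulated statistics with 50,000
permutations, while its tests run smaller.

## Known limitations

* At moderate data sizes the $G^2$ surface can hold competitive local
  minima with qualitatively different parameter readings: a high-gain
  ($\mu_C b$), low-$\alpha$ (wide starting points) solution mimics the
  accuracy and much of the RT structure of a lower-gain, tighter-start
  solution, because both lie near the same accuracy isocline and the
  discriminating information (fast-error CAF bins, error-RT shape) is
  thin. Multi-start optimisation with diverse finalists mitigates but
  cannot guarantee escape; fitted parameters from a single dataset of a
  few thousand trials per condition should be read with this degeneracy
  in mind.
* No trial-to-trial drift variability, collapsing boundaries, or
  non-Euler exact first-passage sampling: the model of record is Euler
  Monte Carlo.
* No closed-form likelihood: all inference is simulation-based, so fitted
  $G^2$ values carry Monte-Carlo noise of order a few percent at the
  default simulation sizes.
* Individual-participant fitting is possible by subsetting the data but no
  hierarchical machinery is provided; the estimator mirrors the
  aggregated-data approach of the source work.
* The G^2 statistic with the printed absolute value does not have a
  $\chi^2$ calibration; it is used comparatively (across models on the
  same data), never as an absolute goodness-of-fit test.
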