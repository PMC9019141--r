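---
title: "Multistate live-recapture/dead-recovery survival: model and design notes"
author: "owlcmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multistate live-recapture/dead-recovery survival: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(owlcmr)
```

## The model

`owlcmr` estimates survival of radio-tagged adult birds (the motivating
system is a little owl population) from *biweekly encounter histories*:
for each fortnightly occasion an individual is coded `1` (observed
alive), `2` (recovered dead), or `3` (neither). Three latent states
drive the data:

1. **alive**,
2. **recently dead and recovered** — the bird died in the preceding
   fortnight and its transmitter or remains were found,
3. **dead and gone** — recently dead but unrecovered, or dead for longer
   than one fortnight (absorbing).

Over one interval a live bird survives with probability $s$, or dies and
is recovered with probability $(1-s)\,r$, or dies unrecovered with
probability $(1-s)(1-r)$; both dead states feed the absorbing state.
Observation is imperfect only for live birds: state 1 emits code `1`
with detection probability $p$ and code `3` otherwise, state 2 always
emits `2`, state 3 always emits `3`. The likelihood of a history is the
hidden-Markov *forward* sum over latent paths, conditioned on the bird
being alive at first capture (no recruitment process is modelled, as
birds are caught at nests as breeders). `history_loglik()` implements
the scaled forward recursion; `brute_force_loglik()` enumerates all
latent paths for short histories and is used throughout the tests as an
independent oracle, together with an equivalent reparameterization that
moves recovery from the transition to the emission step.

Survival is modelled on the logit scale with two *periods* per study
year: the breeding season (BS, May–August) and the rest of the year
(REST, September–April). The period-specific part of the linear
predictor holds the intercept and the focal effects — sex,
food-supplementation of the brood, proportion of food-rich habitat
around the nest (standardized), and the habitat-by-supplementation
interaction; clutch size (standardized), body mass (deviation from the
sex mean in 10 g units), a linear-plus-quadratic age polynomial and
fixed year effects (reference 2010) are shared between periods.
Detection has two era intercepts — the 2009 pilot season, when
transmitter loss was high, versus all later years — plus a sex effect;
dead-recovery probability $r$ is constant.

## Calendar conventions

The source analysis defines the period boundaries but not the occasion
counts. We discretize a study year (1 May–30 April) into 26 fortnights:
9 BS (May–August is ≈8.8 fortnights, rounded up) followed by 17 REST.
An interval between occasions $t$ and $t+1$ carries the period and year
label of its *starting* occasion, which makes each study year contribute
exactly 9 BS and 17 REST intervals — the same counts used for the
cumulative survival products. Sensitivity of derived annual survival to
the neighbouring 8/18 split is below 0.02 (checked in the test suite).
Age increments by one year at each study-year boundary.

Occasion indices are 1-based; histories are stored from occasion 1 with
`3` before first capture, and the likelihood conditions on first
capture. A bird dying in interval $(t, t+1)$ can only be recovered at
occasion $t+1$: the "recently dead" state lasts one fortnight, the
standard coding for dead-recovery data at this resolution.

## Covariate scaling

`scale_covariates()` reproduces the analysis scaling: habitat and clutch
size are standardized to mean 0, sd 1 (sample sd, $n-1$) across the
dataset; body mass becomes $(\text{mass} - \text{sex mean})/10$ g with
default sex means 158.5 g (F) and 152.8 g (M); age enters as raw years
and years². Raw (uncentred) age coding is used because it reproduces the
published derived survival values by plug-in; whether the original code
centred age is not stated. Scaling constants are returned so they can be
pinned in a configuration and reapplied to new data.

## Inference

Two fitting routes target the same marginalized likelihood:

* `fit_mle()` — BFGS from a neutral start (coefficients 0, $r = 0.5$,
  $r$ optimized on the logit scale), standard errors from the inverse
  observed information with a delta-method back-transform for $r$. This
  is the fast path used for parameter-recovery studies.
* `fit_mcmc()` — componentwise adaptive random-walk Metropolis.
  Defaults mirror the original run: 3 chains, a 10,000-iteration
  adaptive phase, 100,000 iterations with 50,000 burn-in, no thinning.
  Proposal scales adapt toward 44% acceptance in blocks of 50 iterations
  and are frozen after the adaptive phase, so the recorded chains are
  genuinely Markov. Sampling the marginal likelihood rather than
  augmenting latent states targets the identical posterior at a small
  fraction of the cost at these problem sizes.

The original priors are in supplementary material not reproduced here;
we default to Normal(0, $\sqrt{10}$) on all logit-scale coefficients and
Uniform(0,1) on $r$ — standard vague choices for this model family — and
`prior_sd` is configurable. Convergence is monitored with the classic
(non-rank-normalized) Gelman–Rubin potential scale reduction factor;
`summarize_posterior()` reports posterior means, equal-tailed 95%
credible intervals and the *f*-statistic (the proportion of draws on the
same side of zero as the mean; draws exactly at zero are excluded from
both sides, a measure-zero event under the model).

Parameters that a design cannot identify — year effects for years absent
from the observed occasions, and the 2009 detection era when 2009 is not
in the calendar — are automatically excluded from the default free set.

## Derived quantities

Derived survival uses the published figure-caption convention: age 3,
standardized covariates at 0, and a *mean year effect* taken as the
arithmetic mean of the five year coefficients on the logit scale
(averaging on the logit rather than probability scale reproduces the
printed values within tolerance). `annual_survival()` multiplies the
back-transformed biweekly rates through 9 BS and 17 REST fortnights;
`supplementation_contrast()` differences annual survival between fed and
unfed profiles.

```{r derived}
th <- theta_published()
round(c(
  F_unfed = annual_survival(th, prediction_profile("F", fed = 0))$annual,
  M_unfed = annual_survival(th, prediction_profile("M", fed = 0))$annual,
  F_fed   = annual_survival(th, prediction_profile("F", fed = 1))$annual,
  M_fed   = annual_survival(th, prediction_profile("M", fed = 1))$annual
), 3)
```

Two estimands must not be confused: the plug-in value (derived function
at the posterior means) and the posterior mean of the derived quantity.
`posterior_derived()` computes the latter, draw-by-draw. For
uncertainties on the scale of the reported credible intervals the Jensen
gap between the two is below 0.05 for annual survival (checked on
simulated posteriors), which is why plug-in reproduction of reported
annual values is tested at ±0.05.

## Synthetic data

`simulate_individuals()` and `simulate_histories()` generate data with
the study's structure: 125 adults (67 F / 58 M), supplementation at the
brood-level rate 38/104 applied per individual (brood structure is not
modelled — the survival model operates per adult), staggered entry at
the first occasion of an entry year, habitat as a truncated-normal
proportion with mean 0.25, treatment-specific clutch means (3.65 / 3.28),
sex-specific mass means, and ages 1–8 skewed toward yearlings (unringed
birds were assumed one year old). The habitat sd (0.18) is derived from
the reported standard error of the experimental-group mean
(0.03 × √38); the reported control-group figure implies an impossible
spread for a proportion and was judged a misprint. Clutch sizes are
truncated Poisson draws (≥1); the real distribution is narrower, which
only makes simulated clutch effects slightly easier to detect. Habitat
is simulated on the raw proportion scale and standardized by the same
code path as real data.

What the simulator does *not* emulate: brood-level clustering (mates
share a territory and treatment), individual detection heterogeneity
beyond sex and era, within-year variation in entry timing, and
transmitter failure as a separate process. Passing recovery tests
therefore demonstrates correctness of the estimation machinery under the
model, not robustness to these real-data features.

`recovery_experiment()` wires simulate → fit → compare into one call and
flags whether each generating value falls inside its 95% interval.

## Numerical choices and degenerate inputs

* The forward recursion rescales at every step, so long histories do not
  underflow; a history whose observation is impossible under the
  parameters returns $-\infty$ rather than an error.
* `standardize()` refuses constant vectors; `parameter_vector()` refuses
  $r \notin (0,1)$ and non-finite coefficients.
* A history captured at the final occasion contributes log-likelihood 0.
* An empty history set has likelihood 0 and is accepted by `fit_mcmc()`
  (prior-only run, used to validate the sampler) but rejected by
  `fit_mle()`.
* Constant MCMC chains yield an Rhat of 1 with a warning rather than
  0/0.

## Problem sizes

The shipped tests and the acceptance script run at desk scale, chosen so
the full suite completes in a few minutes: likelihood-oracle checks on
all valid histories of span ≤ 4 under 100 random parameter draws;
simulate–refit with 500 individuals × 26 occasions (MLE, all 17
identifiable parameters); MCMC convergence on 40 individuals × 10
occasions with 3 × 2,000 iterations; recovery-probability consistency at
n ∈ {150, 600} over 12 seeds. Posterior-quality studies at the original
run length (3 × 100,000 iterations) are a matter of passing a larger
`mcmc_config()`.

## Known limitations

* Recovery windows longer than one fortnight are not modelled; how the
  field data coded late recoveries is unknown.
* Tag loss is absorbed into era-specific detection, not modelled as a
  state.
* Year is a fixed effect; no random effects or model selection (WAIC,
  reversible jump) are provided.
* The detection era is matched on the occasion's calendar year, not the
  cohort's entry year; with the pilot season confined to 2009 the two
  coincide for all but year-boundary occasions.
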