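# owlcmr

Multistate live-recapture / dead-recovery survival models for biweekly
encounter histories, with Bayesian (adaptive Metropolis) and
maximum-likelihood fitting, derived seasonal and annual survival, and a
seeded synthetic-data generator for parameter-recovery studies.

The package is built for analyses of radio-tracked birds — the
motivating system is a population of adult little owls (*Athene noctua*)
followed through the annual cycle — where relocations are summarized
into fortnightly codes: `1` observed alive, `2` recovered dead, `3`
neither. It is aimed at quantitative ecologists who want a
self-contained, testable implementation of this model class: the
likelihood, the sampler, the derived quantities and the simulator are
all ordinary R functions.

## The model

Three latent states: alive (1), recently dead and recovered (2), dead
and gone (3, absorbing). Per biweekly interval, with survival *s* and
recovery probability *r*, the transition matrix is

```
          alive        recovered      gone
alive   [   s        (1-s) r      (1-s)(1-r) ]
recov   [   0            0            1      ]
gone    [   0            0            1      ]
```

and observation is imperfect only for live birds (detection *p*; a
recovered carcass is always coded `2`, the absorbing state never seen).
The likelihood of a history is the hidden-Markov forward sum over
latent paths, conditioned on first capture.

Survival is modelled on the logit scale with period-specific effects
for the breeding season (9 fortnights, May–August) and the rest of the
year (17 fortnights, September–April):

logit *s* = intercept(period) + male(period) + fed(period) +
habitat_z(period) + habitat_z x fed(period) + clutch_z + mass_dev10 +
age + age² + year effect (reference 2010).

Detection has era intercepts (2009 pilot season vs later years) plus a
sex effect; *r* is constant. See the vignette
(`vignettes/multistate-survival.Rmd`) for conventions and design notes.

## Worked example

Simulate a study-structured dataset from the fitted model's posterior
means, refit by maximum marginal likelihood, and derive annual survival:

```r
library(owlcmr)

th <- theta_published()                  # fitted posterior means
cfg <- sim_config(n_individuals = 500, n_years = 1, start_year = 2010)
rec <- recovery_experiment(th, cfg, fit_mode = "mle", t_max = 26, seed = 7)
rec$table[rec$table$parameter %in% c("recovery_r", "surv_intercept_BS"), ]
#>           parameter truth  estimate     se     lo     hi covered
#> 3        recovery_r 0.623 0.6341    0.0270 0.5812 0.6869    TRUE
#> 4 surv_intercept_BS 1.661 1.6446    0.1890 1.2741 2.0151    TRUE
```

Both generating values are recovered within two standard errors: the
dead-recovery probability (the chance a death is found) and the
breeding-season survival intercept on the logit scale.

```r
round(c(
  F_unfed = annual_survival(th, prediction_profile("F", fed = 0))$annual,
  M_unfed = annual_survival(th, prediction_profile("M", fed = 0))$annual,
  F_fed   = annual_survival(th, prediction_profile("F", fed = 1))$annual,
  M_fed   = annual_survival(th, prediction_profile("M", fed = 1))$annual
), 2)
#> F_unfed M_unfed   F_fed   M_fed
#>    0.47    0.61    0.65    0.75
```

These are plug-in annual survivals (age 3, covariates at their means,
logit-mean year effect; 9 + 17 fortnights): parents of food-supplemented
broods survive the year substantially better, in both sexes.

A thin CLI wraps the same functions:

```sh
exec/owlcmr simulate --seed 1 --out-histories h.csv --out-covariates c.csv --out-truth t.csv
exec/owlcmr derive --out derived.csv
```

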