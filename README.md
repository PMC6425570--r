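# upaest

Joint Bayesian estimation of pregnancies, induced abortions, miscarriages
and pregnancy intentions for women aged 15–49, by country and five-year
period (six periods, 1990–2019), with aggregation to regional and global
levels.

## The problem and the model

National estimates of abortion incidence and unintended pregnancy must be
assembled from heterogeneous, imperfect sources: official statistics of
varying completeness, surveys of women that under-report abortion,
indirect facility-based estimates (AICM), and intention surveys that
differ in scope, instrument and recall window. `upaest` implements an
estimation protocol for exactly this situation, aimed at demographers and
reproductive-health researchers.

The core is a demographic accounting model over six population groups
*f* (married/unmarried × unmet need / using contraception / no
contraceptive need). With `w_fct` women in group *f*, country *c*, period
*t*, annual pregnancy risk `ω_fct` and abortion propensity `α_fct`:

```
Ω_fct = w_fct · ω_fct · h          (pregnancies; h = 5-year period width)
Ψ_ct  = Σ_f Ω_fct · α_fct          (induced abortions)
M_ct  = Ψ_ct/10 + B_ct/5           (miscarriages)
pregnancies = 1.2·births + 1.1·abortions
```

Pregnancies of unmet-need and contracepting women are unintended;
pregnancies of no-need women are intended. Latent `log ω` and
`logit(1.1·α)` surfaces get hierarchical priors — group effects, country
baselines pooled within modelling groups, covariate effects, and a
first-order random walk over periods — and every datum enters the
likelihood as a typed observation produced by two classification rule
engines: a **point** (Gaussian on the log/logit scale, right-truncated for
AICM complications), a **minimum**/**maximum** (soft bound), or an
**interval** (censored Gaussian). Survey under-reporting is handled by
regional inflation factors estimated inside the model; recall bias in
intention surveys by regional random intercepts. The posterior is sampled
by a Metropolis-adjusted HMC sampler with analytic gradients.

## Worked example

Simulate a small world, classify its datums, fit, and report:

```r
library(upaest)

truth <- generate_world(world_config(n_regions = 2, countries_per_region = 3,
                                     seed = 11))
raw <- generate_observations(truth, obs_config(seed = 12))
obs <- bind_observations(
  classify_abortion_data(raw$abortion, raw$regions_with_underreporting),
  classify_intention_data(raw$intention, raw$birth_records))
table(obs$bound)
#> interval  minimum    point
#>        5        9       34

cfg <- truth_model_config(truth, sampler = list(chains = 1, adapt = 400,
                                                burnin = 200, iter = 800),
                          seed = 5)
post <- fit(build_model(obs, truth$exposure, cfg))
post
#> upa_posterior: 800 draws (1 chains), 6 countries x 6 periods
#>   mean acceptance: 0.94

glob <- report_indicators(post, "global")
subset(glob, period == 2015 & indicator %in%
         c("abortion_rate", "pct_pregnancies_unintended"))[, 1:6]
#>      unit period                  indicator  point lower95 lower80
#> 24 global   2015 pct_pregnancies_unintended 42.024  39.539  40.271
#> 36 global   2015              abortion_rate  9.567   8.274   8.666
```

(`abortion_rate` is abortions per 1,000 women aged 15–49 per year;
`pct_pregnancies_unintended` is the posterior percent of pregnancies that
were unintended; `point` is the posterior median and the other columns are
80%/95% interval endpoints. Numbers are for this synthetic world, not for
any real country.) The full table carries all fourteen published
indicators per unit and period. `run_pipeline()` orchestrates
simulate → classify → fit → report with a YAML configuration and writes
the classification audit trail, indicator tables, diagnostics and a run
manifest; `inst/cli/upaest` is a thin command-line front end over it.

`validate_holdout()` implements random-subset and leave-country-out
validation, and `recovery_report()` scores parameter recovery against a
synthetic truth. See the methods vignette (`vignettes/methods.Rmd`) for
the full model description, priors, and design choices.

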