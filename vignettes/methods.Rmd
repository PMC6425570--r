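---
title: "Models and methods for estimating pregnancies, abortions and pregnancy intentions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for estimating pregnancies, abortions and pregnancy intentions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(upaest)
```

## The estimation problem

Reliable national estimates of pregnancies, induced abortions and the
intended/unintended composition of pregnancies are hard to produce because
the underlying data are heterogeneous and imperfect: abortion counts come
from official statistics of varying completeness, from surveys of women
that under-report abortion, and from indirect facility-based methods;
pregnancy-intention data come from surveys that differ in scope,
instrument, recall window and access to microdata. `upaest` implements a
joint estimation protocol built around three components:

1. a **demographic accounting model** over six population groups of women
   aged 15--49;
2. two **classification rule engines** that turn every raw datum into a
   typed observation (point, minimum, maximum or interval) with explicit
   error components;
3. a **Bayesian hierarchical time-series model** that combines all typed
   observations into country-period estimates with uncertainty, pooled
   across countries and smoothed across five-year periods (six periods,
   1990--2019).

## Demographic accounting

Women aged 15--49 in country $c$ and period $t$ are partitioned into six
groups $f$: the cross of marital status (married, including cohabiting
unions, vs unmarried) with contraceptive-need status (unmet need, using
contraception, no need). With $w_{fct}$ women in a group and an annual
pregnancy risk $\omega_{fct}$, expected pregnancies are
$\Omega^f_{ct} = w_{fct}\,\omega_{fct}\,h$ (with $h = 5$ years the period
width; risk is defined per woman-year), and abortions are
$\Psi^f_{ct} = \Omega^f_{ct}\,\alpha_{fct}$, where $\alpha$ is the
group-specific probability that a pregnancy ends in induced abortion.
Totals sum over groups: $\Omega_{ct} = \sum_f \Omega^f_{ct}$,
$\Psi_{ct} = \sum_f \Psi^f_{ct}$.

Miscarriages (spontaneous fetal losses after five weeks of gestation,
including stillbirths -- no separate stillbirth row is kept) follow the
life-table-derived ratios of one miscarriage per ten induced abortions and
one per five live births, $M = \Psi/10 + B/5$, equivalent to the identity

$$\text{pregnancies} = 1.2\,\text{births} + 1.1\,\text{abortions}.$$

Implied live births per group are solved exactly from this identity,
$b^f = (\Omega^f - 1.1\,\Psi^f)/1.2$, which makes conservation
($\Omega = b + \Psi + M$) hold to machine precision at group level. All
counts are real-valued expected counts, since they enter a continuous
likelihood.

Intention is attached to groups: pregnancies to women with unmet need or
using contraception are unintended-source, pregnancies to women with no
contraceptive need are intended-source. The published indicator table
(14 rows) reports annualized rates per 1,000 women aged 15--49 and the
percentage indicators; the percent of unintended pregnancies ending in
abortion uses unintended-source groups in both numerator and denominator,
so that abortions of intended pregnancies (modelled, but small) do not
contaminate the indicator.

## Classification of abortion data

Each abortion datum is classified before it can inform the model.
Special-population samples are excluded. Published studies without a
national probability sample receive an additional error-variance
component; surveys reporting subgroup breakdowns receive another
(under-reporting may vary by subgroup). Surveys of women yield a point
estimate linked to a regional under-reporting *inflation factor* when the
region has paired survey/registry information, and a minimum estimate
otherwise. AICM (abortion incidence complications method) studies
contribute the product of treated complications and a survey-derived
multiplier, with separate variance components for each; the complications
error is right-truncated at the total complications including those from
miscarriages, and the modified AICM (which adds a legal-abortion count)
becomes a minimum estimate with a third component.

Official statistics pass through six questions in fixed order; the first
trigger fixes the datum as a minimum estimate: legal abortion not broadly
available; acknowledged completeness below 90%; the count falls below a
women's-survey estimate (which flags all of that country's official years,
unless period-specific quality is established via an explicit per-period
override field); substantial informal-sector provision; implausibility per
expert review (an input flag, not computed). Otherwise the datum is a
point estimate with a non-sampling error term. Whenever the statistic
includes spontaneous abortions, the reported number $m$ is revised via the
pregnancy identity: with $b$ live births, the induced-abortion count lies
in $[(m - 0.2b)/1.1,\; m]$ (clipped at zero); a point becomes that
interval and a minimum is lowered to the revised value. Unknown
completeness proceeds to the next question: a report that does not
acknowledge incompleteness is treated as claiming completeness.

Error components are additive variances on the transformed scale (log for
counts and rates, logit for percentages); this keeps rates positive and
makes components comparable across indicators. Their default magnitudes
(`classification_config()`) are configuration choices -- the decision
logic fixes which components a datum receives, not how large they are.

## Classification of intention data

Intention datums report the percent of births (preferred) or pregnancies
that were unintended. The classifier excludes special populations, adds a
non-probability component when applicable, uses the survey's own sampling
error when microdata or a published SE is available and the mean sampling
error across the run's surveys otherwise, and flags published datums with
recall periods over one year for the regional recall-bias term (estimated
jointly inside the model, not pre-corrected -- the bias and the
uncertainty of having to model it belong in the posterior).
Antenatal-clinic samples are recorded against the births denominator,
because abortion is an improbable outcome in that sampling frame.

Scope drives the targets: all-women surveys inform both the all-women
percent and the percent of marital births intended; ever-married surveys
inform the marital percent; currently-married surveys inform the marital
percent only when recent births are identifiable, and otherwise provide a
maximum on the percent intended among all women -- stored as a *minimum on
the percent unintended*, keeping a single indicator orientation in the
likelihood. Marital observations always carry a marital-subgroup error
component. Surveys using the London Measure of Unplanned Pregnancy enter
as an interval: the traditional percent unintended lies between the
percent unwanted and the percent unwanted plus ambivalent (the garbled
alternative readings collapse to this one once the ambivalent category is
taken as the mixture of would-be intended and would-be unintended
conceptions). Microdata without a marital history yield an interval on the
marital percent computed from birth records: the range is the minimum and
maximum over *all* assignments of ambiguous post-union births (attained by
assigning all ambiguous intended births to marital and all ambiguous
unintended ones to nonmarital, or vice versa), so any mixed assignment is
contained -- a wider but safer reading than using only the two
all-or-nothing assignments.

## The hierarchical model

Both latent surfaces share one linear structure on transformed scales:

$$\eta_{fct} = a_f + b_c + x_{ct}^\top\gamma + d_{ct},$$

with $\omega_{fct} = \exp(\eta^\omega_{fct})$ and
$\theta_{fct} = \mathrm{logit}^{-1}(\eta^\alpha_{fct})$, where
$\theta = 1.1\,\alpha$ is the share of pregnancies *not* ending in a live
birth. Modelling $\theta$ rather than $\alpha$ on the logit scale keeps
implied births nonnegative for every parameter value ($\alpha < 1/1.1$ is
exactly the condition for nonnegative implied births under the miscarriage
ratios); $\alpha$ is recovered as $\theta/1.1$. The propensity is modelled
for all six groups, including the intended-source groups (where it is
small); the percent-of-unintended-pregnancies indicator is computed from
unintended-source groups only.

* $a_f$: population-group effects with informative independent normal
  priors (configurable means, SD 0.3). No sum-to-zero constraint is
  imposed; the level is softly identified through the hierarchy, and the
  sampler handles the resulting flat direction exactly (below).
* $b_c$: country baselines, exchangeable within *modelling groups*
  (countries whose statistical relationships are expected to be similar;
  these may differ from geographic regions), $b_c \sim N(m_{g(c)}, \tau^2)$,
  with group means $m_g$ exchangeable around a world mean and $\tau$ given
  a half-normal prior (scale 0.3).
* $\gamma$: coefficients of candidate covariates (GDP per capita, HDI,
  female literacy, gender inequality, urban population, legal abortion
  status), standardized to mean 0, SD 1 within the run; priors
  $N(0, 0.3^2)$.
* $d_{ct}$: a first-order random walk over the six periods ($d_{c1} = 0$)
  with estimated innovation SD, half-normal prior with scale 0.07 per
  five-year step -- unexplained country trends are smooth but not static.

UNPD live births enter as a Gaussian likelihood,
$B_{ct} \sim N(\sum_f b^f_{ct}, (\mathrm{cv}\cdot B_{ct})^2)$ with a
default coefficient of variation of 5%: birth counts are themselves
estimates (roughly 1--3% uncertain where civil registration is complete,
5--10% elsewhere), so an exact constraint would be overconfident. Missing
births (`NA`) simply contribute nothing.

Each classified observation contributes on the transformed scale:

* **point**: Gaussian with variance equal to the sum of its error
  components plus the delta-method sampling variance for percentages;
  right-truncated observations (AICM) use the renormalized truncated
  Gaussian, which is asymmetric in the latent value;
* **minimum**: $\log\Phi((\eta - y)/s)$; **maximum**: mirrored;
  **interval**: the log probability that a Gaussian measurement with SD
  $s$ centred at the latent value lands in the interval. The soft-bound SD
  $s$ (`bound_softness`, default 0.15) keeps the posterior smooth for the
  gradient-based sampler; hard bounds are the $s \to 0$ limit. Quality
  components attached to a pure bound are recorded in the audit trail but
  do not enter the bound term, whose scale is $s$ alone.

Survey observations linked to under-reporting compare the observed value
against the latent value *divided by* the regional inflation factor
$F_r \ge 1$; $\log F_r$ has a lognormal prior (median factor
$e^{0.3} \approx 1.35$), estimated hierarchically from regions where
surveys coincide with reliable statistics. Recall-flagged intention
observations are shifted by regional recall-bias intercepts
$r_j \sim N(\mu_r, \sigma_r^2)$ on the logit scale, with the mean bias
and its spread estimated jointly.

Observations with a pregnancies denominator are related to the model
through the accounting composition (unintended pregnancies over total
pregnancies), not through a fixed conversion factor.

## Computation

The posterior is sampled with a Metropolis-adjusted Hamiltonian Monte
Carlo sampler written for this model: analytic gradients (verified against
numerical differentiation in the test suite) drive leapfrog trajectories;
the step size is tuned by dual averaging (target acceptance 0.8) and a
diagonal mass matrix is estimated during warmup; every trajectory ends in
an exact accept/reject step, so the invariant distribution is the exact
posterior regardless of tuning. Three ingredients matter for this
posterior's geometry:

* the births constraint ties group effects, baselines and random-walk
  terms together; the likelihood is exactly invariant under the collective
  shift $a \to a + \delta$, $b \to b - \delta$ (optionally with
  $m \to m - \delta$), so the sampler interleaves exact Gibbs draws along
  these directions (their conditionals involve only the priors and are
  Gaussian);
* half-normal SDs are sampled "unfolded": $s \sim N(0, \text{scale})$
  unconstrained with the SD taken as $|s|$ -- the same distribution,
  without a boundary or a heavy transformed-scale tail;
* the random walk is non-centred (unit innovations scaled by the
  innovation SD), and country-mean covariate effects are absorbed into
  the baselines' prior means, which decorrelates $\gamma$ from $b$.

Seeded runs are bit-for-bit reproducible. Convergence is flagged (not
silently ignored) via split-chain potential scale reduction factors and
effective sample sizes on the hyperparameters. An independent JAGS
implementation of the identical joint density is kept in the test suite as
a cross-engine oracle.

Aggregation is draw-by-draw: counts are summed over a region's (or the
world's) countries within each posterior draw and rates/percentages are
recomputed from the pooled counts -- never averaged across countries -- so
the global totals equal the sum over regions in every draw and the
accounting identities hold for every reported draw.

## Validation and covariate selection

`validate_holdout()` refits the model after removing either a random
subset of observations or one country's entire data, and scores the
held-out datums against their posterior predictive distributions: median
prediction error (bias), RMSE, and empirical coverage of the 80% and 95%
predictive intervals on the transformed scale. Pure bounds are held out
but not scored. `select_covariates()` ranks covariate subsets by holdout
RMSE (ties: absolute bias, then fewer covariates) on a shared holdout
split, and warns on collinear candidates with the condition number.

## The synthetic-data generator

`generate_world()` draws a world from the model's own generative process:
every hyperparameter (group effects, group means, country baselines,
coefficients, innovation SDs, inflation factors, recall biases) comes from
the same distributions the model uses as priors, so posterior intervals
are calibrated by construction and parameter-recovery coverage is a sharp
test of the implementation. Exposures use plausible magnitudes (country
sizes lognormal around 200,000 women aged 15--49; group shares near
typical survey compositions with jitter; 1% annual growth); covariates are
standard normal; UNPD births are the implied births times lognormal noise
with the configured CV.

`generate_observations()` realizes the datum taxonomy. Countries receive
data regimes in proportion blocks (complete registry, survey with
under-reporting, incomplete registry, AICM setting, or no data);
categorical features (datum presence, special populations, probability
sampling, subgroup breakdowns, microdata, recall windows, instruments,
denominators) follow low-discrepancy streams keyed by country, period and
feature, so the configured rates are respected and the default
configuration exercises every branch of both decision trees
deterministically. The imperfections mirror what the classifiers expect:
incomplete registries report a known fraction flagged through one of the
five official-statistic questions; statistics including spontaneous
abortions contain an *unknown share* of the miscarriages (which is why the
classifier treats the adjusted value as an interval, not as truth); AICM
complications are skewed downward by imperfect miscarriage subtraction and
bounded by the total complications; surveys divide the truth by the
regional inflation factor; recall-biased surveys shift the logit by the
regional intercept.

What the generator does *not* emulate: real-country magnitudes or
published estimates, age structure below the 15--49 aggregate, correlated
covariates, non-stationary data availability, or misclassified datum
provenance (a datum's flags are always truthful). Passing recovery tests
therefore demonstrates internal consistency of model, classifier and
sampler under the stated imperfection model -- not correctness of any
real-world estimate.

## Problem sizes and defaults used by the test suite

The package's own validation runs at desk scale, chosen as the smallest
sizes that exercise all structure: recovery uses 4 regions x 5 countries x
6 periods with short single-chain runs across multiple seeds (pooling
coverage over several hundred parameters); holdout and engine-comparison
checks use 2 x 2 or 2 x 3 country worlds with 2-3 periods. Interval
coverage at these run lengths carries Monte-Carlo error of a few
percentage points, which the pooled checks account for.

## Known limitations

* The likelihood treats classified intervals as censored-Gaussian regions;
  datums whose true position inside the interval is systematically at one
  end will be pulled toward the middle. This is the price of the
  conservative interval reading and is shared by the protocol itself.
* Modelling groups, regions and all prior magnitudes are run
  configuration; the package ships defaults, not recommendations for any
  real analysis.
* The recall-bias and inflation-factor hierarchies borrow strength across
  regions; with no informative region at all they return their priors.
* Country suppression for data-free countries is a reporting flag
  (suppress countries with no non-excluded datum), not an automated
  information criterion.
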