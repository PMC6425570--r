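Package: upaest
Title: Hierarchical Bayesian Estimation of Pregnancy, Abortion and
    Pregnancy-Intention Levels and Trends
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Demographic accounting and Bayesian hierarchical time-series
    estimation of pregnancies, induced abortions, miscarriages and pregnancy
    intentions for women aged 15-49, by country and five-year period
    (1990-2019). Exposures are split into six population groups (married and
    unmarried women with unmet need for contraception, using contraception,
    or with no contraceptive need); group pregnancy risks and propensities
    for a pregnancy to end in abortion are modelled jointly on log and logit
    scales with covariate effects, hierarchical pooling across countries
    within modelling groups, and random-walk smoothing over periods.
    Heterogeneous abortion and pregnancy-intention data are converted into
    typed observations (point, minimum, maximum, interval) by rule engines
    that encode source quality, completeness, indirect (AICM) estimation,
    survey under-reporting via regional inflation factors, and recall bias.
    Includes a synthetic-data generator for simulation-based validation,
    holdout model validation, covariate selection, and publication-shaped
    indicator reporting at national, regional and global levels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    coda,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    rjags,
    withr
Config/testthat/edition: 3
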