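#' Default prior hyperparameters
#'
#' Weakly informative priors for the hierarchical model, all on the
#' transformed scales (log pregnancy risk; logit of the non-birth share of
#' pregnancies, see [build_model()]). Population-group effects get
#' informative priors around configurable means; modelling-group means are
#' exchangeable around a world mean; country baselines are exchangeable
#' within modelling groups with an estimated SD (half-normal prior);
#' random-walk innovation SDs get half-normal priors; covariate
#' coefficients get mean-zero normal priors; regional log inflation factors
#' get a lognormal prior (factor strictly above 1); regional
#' recall-bias intercepts are exchangeable around an estimated mean bias.
#'
#' @return Named list of hyperparameters.
#' @export
default_priors <- function() {
  list(
    # population-group effects (enumeration order of population_groups())
    group_effects_omega = c(0.7, -0.6, 1.0, 0.0, -1.3, -0.9),
    group_effects_alpha = c(0.3, 0.7, -2.3, 0.9, 1.3, -2.7),
    sd_group_effect = 0.3,
    # world means and SDs of the modelling-group means
    mu_world_omega = log(0.05), sd_world_omega = 0.4,
    mu_world_alpha = stats::qlogis(0.35), sd_world_alpha = 0.4,
    # half-normal scale of the country-within-group SD
    sd_country_scale = 0.3,
    # covariate coefficients ~ N(0, coef_sd^2)
    coef_sd = 0.3,
    # half-normal scale of the random-walk innovation SD
    rw_sd_scale = 0.07,
    # regional log inflation factor ~ lognormal (factor at least 1, with a
    # right-skewed tail for heavily under-reported regions)
    infl_meanlog = log(0.3), infl_sdlog = 0.5,
    # recall bias (logit percent-unintended scale): regional intercepts
    # ~ N(mu_rb, sd_rb^2); mu_rb ~ N(recall_mu0, recall_mu_sd^2),
    # sd_rb ~ half-normal(recall_sd_scale)
    recall_mu0 = -0.25, recall_mu_sd = 0.3, recall_sd_scale = 0.15,
    # coefficient of variation of the UNPD live-birth likelihood
    births_cv = 0.05)
}

#' Model configuration
#'
#' @param countries Data frame with columns `country`, `modeling_group`,
#'   `region`: every country belongs to exactly one modelling group (the
#'   set of countries whose statistical relationships are pooled; may
#'   differ from geographic subregions) and one region (used for inflation
#'   factors and recall bias).
#' @param covariates Numeric array `[C, T, K]` of candidate covariates per
#'   country-period (e.g. GDP per capita, HDI, female literacy, gender
#'   inequality index, urban population, legal abortion status), with
#'   dimnames on the third margin; or `NULL` for a covariate-free model.
#' @param covariate_names Which covariates enter the model (default all
#'   columns of `covariates`).
#' @param priors List of prior hyperparameters, see [default_priors()].
#' @param bound_softness SD of the soft-bound likelihood on the transformed
#'   scale.
#' @param period_width Period width in years.
#' @param sampler List: `chains`, `adapt`, `burnin`, `iter`, `thin`,
#'   `n_leapfrog` (base leapfrog steps per HMC trajectory).
#' @param seed Integer seed for the sampler.
#' @param standardize_covariates Standardize each covariate to mean 0, SD 1
#'   within the run (default `TRUE`).
#' @return A list of class `upa_model_config`.
#' @export
model_config <- function(countries, covariates = NULL,
                         covariate_names = NULL,
                         priors = default_priors(),
                         bound_softness = 0.15,
                         period_width = 5,
                         sampler = list(chains = 2, adapt = 400,
                                        burnin = 200, iter = 800, thin = 1,
                                        n_leapfrog = 20),
                         seed = 1L,
                         standardize_covariates = TRUE) {
  need <- c("country", "modeling_group", "region")
  if (!all(need %in% names(countries))) {
    stop("countries needs columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(countries$country)) {
    stop("every country must appear exactly once")
  }
  pr <- default_priors()
  pr[names(priors)] <- priors
  sa <- list(chains = 2, adapt = 400, burnin = 200, iter = 800, thin = 1,
             n_leapfrog = 20)
  sa[names(sampler)] <- sampler
  structure(list(countries = countries, covariates = covariates,
                 covariate_names = covariate_names, priors = pr,
                 bound_softness = bound_softness,
                 period_width = period_width, sampler = sa,
                 seed = as.integer(seed),
                 standardize_covariates = standardize_covariates),
            class = "upa_model_config")
}

#' Load a model configuration from YAML
#'
#' The YAML file holds the country table (`countries:` a list of
#' `{country, modeling_group, region}` records), prior overrides, sampler
#' settings, `bound_softness`, `period_width` and `seed`. Covariates are
#' passed separately (they are tabular inputs).
#'
#' @param path Path to a YAML file.
#' @param covariates Optional covariate array (see [model_config()]).
#' @return A `upa_model_config`.
#' @export
read_model_config <- function(path, covariates = NULL) {
  y <- yaml::read_yaml(path)
  countries <- do.call(rbind, lapply(y$countries, function(r) {
    data.frame(country = r$country, modeling_group = r$modeling_group,
               region = r$region, stringsAsFactors = FALSE)
  }))
  args <- list(countries = countries, covariates = covariates)
  for (f in c("priors", "bound_softness", "period_width", "sampler", "seed",
              "covariate_names")) {
    if (!is.null(y[[f]])) args[[f]] <- y[[f]]
  }
  do.call(model_config, args)
}

standardized_covariates <- function(config, n_countries, n_periods) {
  X <- config$covariates
  if (is.null(X)) {
    return(array(0, c(n_countries, n_periods, 0)))
  }
  stopifnot(length(dim(X)) == 3L)
  nm <- dimnames(X)[[3]]
  keep <- config$covariate_names
  if (!is.null(keep)) {
    miss <- setdiff(keep, nm)
    if (length(miss)) stop("unknown covariates: ", paste(miss, collapse = ", "))
    X <- X[, , match(keep, nm), drop = FALSE]
    nm <- keep
  }
  if (config$standardize_covariates && dim(X)[3] > 0) {
    for (k in seq_len(dim(X)[3])) {
      v <- X[, , k]
      s <- stats::sd(v)
      X[, , k] <- if (s > 0) (v - mean(v)) / s else v - mean(v)
    }
  }
  dimnames(X) <- list(NULL, NULL, nm)
  X
}
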