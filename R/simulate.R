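#' Synthetic-world configuration
#'
#' The generator draws a synthetic world from the model's own generative
#' process: hyperparameters (population-group effects, modelling-group
#' means, country baselines, covariate coefficients, random-walk innovation
#' SDs, regional inflation factors and recall-bias intercepts) are drawn
#' from the distributions in `priors`, then exposures, covariates and true
#' rate surfaces are realized per country. All randomness flows from the
#' single mandatory seed, with a separate stream per country so that adding
#' countries does not perturb existing ones.
#'
#' @param n_regions Number of regions.
#' @param countries_per_region Countries per region.
#' @param periods Period start years (default six periods 1990-2015).
#' @param priors Generative hyperparameters; defaults to [default_priors()]
#'   so that the generator matches the model's prior structure exactly.
#' @param active_covariates Covariates with (drawn) nonzero coefficients;
#'   the remaining candidate covariates are generated as pure noise.
#' @param covariate_names All candidate covariates generated per
#'   country-period.
#' @param gamma_omega,gamma_alpha Optional fixed named coefficient vectors
#'   over `active_covariates`; when `NULL` (default) the coefficients are
#'   drawn from the `N(0, coef_sd^2)` prior.
#' @param women_meanlog,women_sdlog Log-normal size of a country's women
#'   aged 15-49 at the first period.
#' @param growth_rate Annual growth rate of exposures across periods.
#' @param group_share_jitter Log-normal jitter SD on the base group shares.
#' @param omega_max Upper plausibility bound passed to [rate_surface()].
#' @param seed Mandatory integer seed.
#' @return A list of class `upa_world_config`.
#' @export
world_config <- function(n_regions = 4L, countries_per_region = 5L,
                         periods = default_periods(),
                         priors = default_priors(),
                         active_covariates = c("gdp_pc", "legal_status"),
                         covariate_names = c("gdp_pc", "hdi",
                                             "female_literacy",
                                             "gender_inequality",
                                             "urban_pop", "legal_status"),
                         gamma_omega = NULL, gamma_alpha = NULL,
                         women_meanlog = log(2e5), women_sdlog = 0.5,
                         growth_rate = 0.01, group_share_jitter = 0.15,
                         omega_max = 5, seed) {
  if (missing(seed)) stop("a seed is mandatory (no implicit randomness)")
  pr <- default_priors()
  pr[names(priors)] <- priors
  bad <- c(pr$sd_group_effect, pr$sd_world_omega, pr$sd_world_alpha,
           pr$sd_country_scale, pr$rw_sd_scale, pr$coef_sd, pr$infl_sdlog,
           pr$recall_mu_sd, pr$recall_sd_scale)
  if (any(bad <= 0)) stop("all generative SDs must be positive")
  stopifnot(all(active_covariates %in% covariate_names))
  structure(list(n_regions = as.integer(n_regions),
                 countries_per_region = as.integer(countries_per_region),
                 periods = as.integer(periods), priors = pr,
                 active_covariates = active_covariates,
                 covariate_names = covariate_names,
                 gamma_omega = gamma_omega, gamma_alpha = gamma_alpha,
                 women_meanlog = women_meanlog, women_sdlog = women_sdlog,
                 growth_rate = growth_rate,
                 group_share_jitter = group_share_jitter,
                 omega_max = omega_max, seed = as.integer(seed)),
            class = "upa_world_config")
}

country_seed <- function(seed, i) (as.integer(seed) * 10007L + i) %% 2147483647L

#' Generate a synthetic world
#'
#' @param cfg A [world_config()].
#' @return A list of class `upa_truth`: `exposure` (`upa_exposure` with
#'   UNPD-style births), `rates` (`upa_rates`), `accounts`
#'   (`upa_accounts`), `X` (standardized covariate array `[C, T, K]`),
#'   `countries` (country / modelling-group / region table), `params` (all
#'   true latent parameters), and the `config`.
#' @export
generate_world <- function(cfg) {
  stopifnot(inherits(cfg, "upa_world_config"))
  pr <- cfg$priors
  R <- cfg$n_regions; C <- R * cfg$countries_per_region
  T <- length(cfg$periods); Fg <- 6L
  countries <- sprintf("C%02d", seq_len(C))
  regions <- sprintf("R%d", ceiling(seq_len(C) / cfg$countries_per_region))
  groups <- sprintf("G%d", ((seq_len(C) - 1L) %% R) + 1L)
  glev <- sort(unique(groups)); rlev <- sort(unique(regions))
  G <- length(glev)
  K_all <- length(cfg$covariate_names)
  act <- match(cfg$active_covariates, cfg$covariate_names)
  set.seed(cfg$seed)
  a_om <- stats::rnorm(Fg, pr$group_effects_omega, pr$sd_group_effect)
  a_al <- stats::rnorm(Fg, pr$group_effects_alpha, pr$sd_group_effect)
  m_om <- stats::rnorm(G, pr$mu_world_omega, pr$sd_world_omega)
  m_al <- stats::rnorm(G, pr$mu_world_alpha, pr$sd_world_alpha)
  tau_om <- abs(stats::rnorm(1, 0, pr$sd_country_scale))
  tau_al <- abs(stats::rnorm(1, 0, pr$sd_country_scale))
  sig_rw_om <- abs(stats::rnorm(1, 0, pr$rw_sd_scale))
  sig_rw_al <- abs(stats::rnorm(1, 0, pr$rw_sd_scale))
  g_om <- g_al <- stats::setNames(numeric(length(act)),
                                  cfg$active_covariates)
  if (is.null(cfg$gamma_omega)) {
    g_om[] <- stats::rnorm(length(act), 0, pr$coef_sd)
  } else g_om[names(cfg$gamma_omega)] <- cfg$gamma_omega
  if (is.null(cfg$gamma_alpha)) {
    g_al[] <- stats::rnorm(length(act), 0, pr$coef_sd)
  } else g_al[names(cfg$gamma_alpha)] <- cfg$gamma_alpha
  log_infl <- stats::rlnorm(R, pr$infl_meanlog, pr$infl_sdlog)
  mu_rb <- stats::rnorm(1, pr$recall_mu0, pr$recall_mu_sd)
  sd_rb <- abs(stats::rnorm(1, 0, pr$recall_sd_scale))
  rb <- stats::rnorm(R, mu_rb, sd_rb)
  gidx <- match(groups, glev)
  # base group shares of women 15-49 (married/unmarried x need status)
  s0 <- c(0.08, 0.35, 0.22, 0.03, 0.12, 0.20)
  women <- array(0, c(Fg, C, T))
  X <- array(0, c(C, T, K_all),
             dimnames = list(NULL, NULL, cfg$covariate_names))
  b_om <- b_al <- numeric(C)
  d_om <- d_al <- matrix(0, C, T)
  for (i in seq_len(C)) {
    set.seed(country_seed(cfg$seed, i))
    b_om[i] <- stats::rnorm(1, m_om[gidx[i]], tau_om)
    b_al[i] <- stats::rnorm(1, m_al[gidx[i]], tau_al)
    if (T > 1) {
      d_om[i, ] <- c(0, cumsum(stats::rnorm(T - 1, 0, sig_rw_om)))
      d_al[i, ] <- c(0, cumsum(stats::rnorm(T - 1, 0, sig_rw_al)))
    }
    X[i, , ] <- stats::rnorm(T * K_all)
    size <- stats::rlnorm(1, cfg$women_meanlog, cfg$women_sdlog)
    shares <- s0 * exp(stats::rnorm(Fg, 0, cfg$group_share_jitter))
    shares <- shares / sum(shares)
    width <- if (T > 1) diff(cfg$periods[1:2]) else 5
    for (t in seq_len(T)) {
      women[, i, t] <- size * shares * (1 + cfg$growth_rate)^(width * (t - 1))
    }
  }
  # standardize covariates within the run; truths are generated on the
  # standardized scale so the model's generative process is matched exactly
  for (k in seq_len(K_all)) {
    v <- X[, , k]
    sdv <- stats::sd(v)
    X[, , k] <- if (is.finite(sdv) && sdv > 0) (v - mean(v)) / sdv else 0
  }
  xb_om <- xb_al <- matrix(0, C, T)
  for (j in seq_along(act)) {
    xb_om <- xb_om + X[, , act[j]] * g_om[j]
    xb_al <- xb_al + X[, , act[j]] * g_al[j]
  }
  eta_om <- eta_al <- array(0, c(Fg, C, T))
  for (f in seq_len(Fg)) {
    eta_om[f, , ] <- a_om[f] + b_om + xb_om + d_om
    eta_al[f, , ] <- a_al[f] + b_al + xb_al + d_al
  }
  rates <- rate_surface(exp(eta_om), stats::plogis(eta_al) / 1.1,
                        omega_max = cfg$omega_max)
  width <- if (T > 1) diff(cfg$periods[1:2]) else 5
  exposure0 <- exposure_surface(women, matrix(1, C, T),
                                countries = countries,
                                periods = cfg$periods)
  accounts <- pregnancy_accounts(exposure0, rates, period_width = width)
  set.seed(country_seed(cfg$seed, C + 1L))
  B <- accounts$births *
    matrix(exp(stats::rnorm(C * T, 0, pr$births_cv)), C, T)
  exposure <- exposure_surface(women, B, countries = countries,
                               periods = cfg$periods)
  structure(list(
    exposure = exposure, rates = rates, accounts = accounts, X = X,
    countries = data.frame(country = countries, modeling_group = groups,
                           region = regions, stringsAsFactors = FALSE),
    params = list(a_om = a_om, a_al = a_al,
                  m_om = stats::setNames(m_om, glev),
                  m_al = stats::setNames(m_al, glev),
                  b_om = b_om, b_al = b_al, tau_om = tau_om,
                  tau_al = tau_al, sig_rw_om = sig_rw_om,
                  sig_rw_al = sig_rw_al, gamma_om = g_om, gamma_al = g_al,
                  d_om = d_om, d_al = d_al,
                  log_infl = stats::setNames(log_infl, rlev),
                  rb = stats::setNames(rb, rlev), mu_rb = mu_rb,
                  sd_rb = sd_rb),
    config = cfg), class = "upa_truth")
}

#' Model configuration matching a synthetic truth
#'
#' Convenience constructor: the country table, active covariates and priors
#' of the world the truth was generated from.
#'
#' @param truth A `upa_truth`.
#' @param covariate_names Covariates to include (default the world's active
#'   covariates).
#' @param priors Prior hyperparameters (default the world's generative
#'   hyperparameters, so model and generator match).
#' @param ... Passed to [model_config()] (e.g. `sampler`, `seed`,
#'   `bound_softness`).
#' @return A `upa_model_config`.
#' @export
truth_model_config <- function(truth,
                               covariate_names =
                                 truth$config$active_covariates,
                               priors = truth$config$priors, ...) {
  width <- if (length(truth$exposure$periods) > 1) {
    diff(truth$exposure$periods[1:2])
  } else 5
  model_config(countries = truth$countries, covariates = truth$X,
               covariate_names = covariate_names,
               priors = priors, period_width = width, ...)
}
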