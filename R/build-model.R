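#' Build the hierarchical model specification
#'
#' Assembles the joint Bayesian model over latent pregnancy risks and
#' abortion propensities from classified observations, an exposure surface
#' and a model configuration. The latent structure, per surface (log
#' pregnancy risk `omega`; logit of the non-birth share of pregnancies,
#' which is 1.1 times the abortion propensity `alpha` -- this link keeps
#' implied live births nonnegative), is
#'
#' `eta[f,c,t] = a[f] + b[c] + X[c,t,] %*% gamma + d[c,t]`
#'
#' with population-group effects `a` (informative priors), country
#' baselines `b` drawn from modelling-group means (information exchanged
#' across countries within the same group), standardized covariate effects
#' `gamma`, and a first-order random walk `d` over the periods with
#' estimated innovation SD. Group exposures map to pregnancies, abortions,
#' implied births and miscarriages through the accounting identities; UNPD
#' live births enter as a Gaussian likelihood with a configurable
#' coefficient of variation (`NA` births are treated as unavailable). Each
#' classified observation contributes a point (Gaussian, possibly
#' right-truncated), minimum, maximum or interval (soft-bound) likelihood
#' term on the transformed scale; survey observations linked to the
#' regional inflation factor are compared against the latent value divided
#' by the factor, and recall-flagged intention observations are shifted by
#' regional recall-bias intercepts.
#'
#' @param obs Classified-observation table (excluded rows are ignored).
#' @param exposure A `upa_exposure` object covering the full grid.
#' @param config A [model_config()].
#' @return An object of class `upa_model`: the data arrays, the prepared
#'   non-excluded observation table `obs` (with resolved indices), the
#'   parameter index map `pars`, `dims`, and the `config`.
#' @export
build_model <- function(obs, exposure, config) {
  stopifnot(inherits(exposure, "upa_exposure"),
            inherits(config, "upa_model_config"))
  countries <- exposure$countries
  periods <- exposure$periods
  ct <- config$countries
  missing_c <- setdiff(countries, ct$country)
  if (length(missing_c)) {
    stop("countries missing from model configuration: ",
         paste(missing_c, collapse = ", "))
  }
  ct <- ct[match(countries, ct$country), ]
  groups_lev <- sort(unique(ct$modeling_group))
  regions_lev <- sort(unique(ct$region))
  group_idx <- match(ct$modeling_group, groups_lev)
  region_idx <- match(ct$region, regions_lev)
  X <- standardized_covariates(config, length(countries), length(periods))
  K <- dim(X)[3]
  C <- length(countries); T <- length(periods)
  pr <- config$priors
  W <- women_total(exposure)
  if (any(W <= 0)) stop("every country-period needs positive exposure")
  obs <- obs[!obs$excluded, , drop = FALSE]
  om <- prepare_obs_data(obs, countries, periods, regions_lev,
                         ct$region, config)
  gint <- group_intention()
  married <- population_groups()$marital_status == "married"
  B <- exposure$births
  sdB <- pr$births_cv * pmax(B, 1)
  lograte_off <- log(W * config$period_width / 1000)
  data <- list(
    F = 6L, C = C, T = T, G = length(groups_lev), R = length(regions_lev),
    K = K, w = exposure$women, pw = config$period_width, B = B,
    sdB = sdB, lograte_off = lograte_off,
    # vectorized views used by the likelihood evaluator
    wmat = matrix(exposure$women, nrow = 6L),
    Bv = as.vector(B), sdBv = as.vector(sdB),
    bmask = !is.na(as.vector(B)),
    lograte_off_v = as.vector(lograte_off),
    X = X,
    unint = gint == "unintended", married = married,
    married_intended = married & gint == "intended",
    group = group_idx, region = region_idx, soft = config$bound_softness,
    priors = pr)
  structure(list(
    data = data, obs = om$obs, obsdat = om$data,
    pars = parameter_index(C, T, length(groups_lev), length(regions_lev), K),
    dims = list(countries = countries, periods = periods,
                groups = groups_lev, regions = regions_lev,
                group_idx = group_idx, region_idx = region_idx,
                covariates = if (K > 0) dimnames(X)[[3]] else character(0),
                X = X, W = W),
    config = config), class = "upa_model")
}

prepare_obs_data <- function(obs, countries, periods, regions_lev,
                             country_region, config) {
  n <- nrow(obs)
  if (n == 0) {
    return(list(obs = obs,
                data = list(n = 0L, ci = integer(0), ti = integer(0),
                            oi = integer(0), ri = integer(0),
                            type = character(0), y = numeric(0),
                            yhi = numeric(0), vtot = numeric(0),
                            utr = numeric(0), seff = numeric(0),
                            infl = logical(0), osign = numeric(0))))
  }
  ci <- match(obs$country, countries)
  if (anyNA(ci)) {
    stop("observation references unknown country: ",
         paste(unique(obs$country[is.na(ci)]), collapse = ", "))
  }
  ti <- match(obs$period, periods)
  if (anyNA(ti)) stop("observation references a period outside the grid")
  ind_codes <- c(abortion_count = 1L, abortion_rate = 2L,
                 percent_births_unintended = 3L,
                 percent_pregnancies_unintended = 4L,
                 percent_marital_births_intended = 5L)
  oi <- ind_codes[obs$indicator]
  if (anyNA(oi)) {
    stop("observation on unknown indicator: ",
         paste(unique(obs$indicator[is.na(oi)]), collapse = ", "))
  }
  ri <- match(obs$region, regions_lev)
  ri[is.na(ri)] <- match(country_region, regions_lev)[ci[is.na(ri)]]
  if (any(obs$inflation_link == "regional_inflation_factor" & is.na(ri))) {
    stop("inflation-linked observation with unknown region")
  }
  osign <- ifelse(obs$recall_flag & oi %in% c(3L, 4L), 1,
                  ifelse(obs$recall_flag & oi == 5L, -1, 0))
  y <- vapply(seq_len(n), function(i)
    obs_transform(obs$indicator[i], obs$value[i]), 0)
  yhi <- vapply(seq_len(n), function(i) {
    if (identical(obs$bound[i], "interval"))
      obs_transform(obs$indicator[i], obs$value_high[i]) else NA_real_
  }, 0)
  vtot <- vapply(seq_len(n), function(i)
    obs_total_variance(obs[i, , drop = FALSE]), 0)
  utr <- vapply(seq_len(n), function(i) {
    if (is.na(obs$truncation[i])) NA_real_
    else obs_transform(obs$indicator[i], obs$truncation[i])
  }, 0)
  type <- ifelse(obs$bound == "point" & is.na(obs$truncation), "pp",
          ifelse(obs$bound == "point", "tp",
          ifelse(obs$bound == "minimum", "mn",
          ifelse(obs$bound == "maximum", "mx", "iv"))))
  if (any(type %in% c("pp", "tp") & !(vtot > 0))) {
    stop("point observation with nonpositive total error variance")
  }
  obs$.ci <- ci; obs$.ti <- ti; obs$.oi <- unname(oi)
  obs$.ri <- ifelse(is.na(ri), 1L, ri)
  obs$.osign <- osign
  oi_u <- unname(oi)
  infl <- obs$inflation_link == "regional_inflation_factor"
  list(obs = obs,
       data = list(n = n, ci = ci, ti = ti, oi = oi_u,
                   ri = ifelse(is.na(ri), 1L, ri), type = type, y = y,
                   yhi = yhi, vtot = vtot, utr = utr,
                   # bound SD: configured softness plus the datum's variance
                   seff = sqrt(config$bound_softness^2 + vtot),
                   infl = infl, infl_num = as.numeric(infl),
                   osign = osign,
                   # precomputed index and type masks
                   lin_idx = (ti - 1L) * length(countries) + ci,
                   i1 = oi_u == 1L, i2 = oi_u == 2L, i3 = oi_u == 3L,
                   i4 = oi_u == 4L, i5 = oi_u == 5L,
                   ip = type == "pp", itp = type == "tp",
                   imn = type == "mn", imx = type == "mx",
                   iiv = type == "iv"))
}

# index map of the unconstrained parameter vector
parameter_index <- function(C, T, G, R, K) {
  blocks <- list(
    a_om = 6L, a_al = 6L, m_om = G, m_al = G, b_om = C, b_al = C,
    gamma_om = K, gamma_al = K, utau_om = 1L, utau_al = 1L,
    usig_om = 1L, usig_al = 1L,
    e_om = C * max(T - 1L, 0L), e_al = C * max(T - 1L, 0L),
    linfl = R, mu_rb = 1L, usd_rb = 1L, zrb = R)
  idx <- list(); pos <- 0L
  for (nm in names(blocks)) {
    nblk <- blocks[[nm]]
    idx[[nm]] <- if (nblk > 0) pos + seq_len(nblk) else integer(0)
    pos <- pos + nblk
  }
  attr(idx, "n") <- pos
  idx
}
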