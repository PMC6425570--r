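# small worlds and short chains keep these fits to a few seconds each

test_that("build_model validates observations against the grid", {
  sim <- tiny_world(seed = 11)
  cfg <- truth_model_config(sim$truth, sampler = fast_sampler, seed = 2)
  bad <- sim$obs[1, , drop = FALSE]
  bad$country <- "XX"
  expect_error(build_model(bad, sim$truth$exposure, cfg), "unknown country")
  bad2 <- sim$obs[!sim$obs$excluded, ][1, , drop = FALSE]
  bad2$indicator <- "made_up"
  expect_error(build_model(bad2, sim$truth$exposure, cfg),
               "unknown indicator")
  m <- build_model(sim$obs, sim$truth$exposure, cfg)
  expect_s3_class(m, "upa_model")
  expect_equal(m$obsdat$n, sum(!sim$obs$excluded))
})

test_that("a prior-only model samples and reproduces the prior", {
  truth <- generate_world(world_config(n_regions = 1,
                                       countries_per_region = 2,
                                       periods = c(1990L, 1995L), seed = 3))
  exposure <- truth$exposure
  exposure$births[] <- NA_real_  # no data at all
  cfg <- truth_model_config(truth,
                            sampler = list(chains = 1, adapt = 300,
                                           burnin = 100, iter = 3000,
                                           n_leapfrog = 15), seed = 4)
  model <- build_model(empty_observations(), exposure, cfg)
  post <- fit(model)
  m1 <- post$draws[, "m_om[1]"]
  pr <- default_priors()
  # prior sd 0.4 with effective sample size ~10^2: tolerance ~3 MC SEs
  expect_lt(abs(mean(m1) - pr$mu_world_omega), 0.15)
  expect_lt(abs(sd(m1) - pr$sd_world_omega), 0.12)
  li <- post$draws[, "log_infl[1]"]
  expect_true(all(li >= 0))  # inflation factors at least 1
})

test_that("seeded fits are reproducible and seeds change the draws", {
  sim <- tiny_world(seed = 11, n_regions = 1, countries_per_region = 2,
                    periods = c(1990L, 1995L))
  cfg <- truth_model_config(sim$truth, sampler = fast_sampler, seed = 9)
  model <- build_model(sim$obs, sim$truth$exposure, cfg)
  p1 <- fit(model)
  p2 <- fit(model)
  expect_identical(p1$draws, p2$draws)
  p3 <- fit(model, seed = 10)
  expect_false(identical(p1$draws, p3$draws))
})

test_that("a one-parameter reduction matches the conjugate closed form and a grid oracle", {
  truth <- generate_world(world_config(n_regions = 1,
                                       countries_per_region = 1,
                                       periods = 1990L, seed = 6))
  exposure <- truth$exposure
  exposure$births[] <- NA_real_
  pr <- default_priors()
  obs <- classified_observation(
    "d1", exposure$countries[1], 1990L, "abortion_count", bound = "point",
    value = 900, components = c(nonsampling_default = 0.04))
  cfg <- truth_model_config(truth, covariate_names = character(0),
                            sampler = list(chains = 1, adapt = 400,
                                           burnin = 100, iter = 4000,
                                           n_leapfrog = 10), seed = 7)
  cfg$covariates <- NULL
  model <- build_model(obs, exposure, cfg)
  # fix everything except the pregnancy-level baseline b_om
  m0 <- pr$mu_world_omega; tau0 <- 0.25
  fix <- list(a_om = pr$group_effects_omega, a_al = pr$group_effects_alpha,
              m_om = m0, m_al = pr$mu_world_alpha,
              b_al = pr$mu_world_alpha, utau_om = tau0,
              utau_al = 0.2, usig_om = 0.05,
              usig_al = 0.05, linfl = log(0.3), mu_rb = -0.25,
              usd_rb = 0.1, zrb = 0)
  post <- fit(model, fix = fix)
  b <- post$draws[, "b_om[1]"]
  # log Psi = b + log k is linear in b: Gaussian likelihood, Gaussian prior
  th <- plogis(pr$group_effects_alpha + pr$mu_world_alpha)
  k <- sum(exposure$women[, 1, 1] * exp(pr$group_effects_omega) * th) / 1.1 *
    model$config$period_width
  y <- log(900); v <- 0.04
  post_prec <- 1 / tau0^2 + 1 / v
  post_mean <- (m0 / tau0^2 + (y - log(k)) / v) / post_prec
  post_sd <- sqrt(1 / post_prec)
  expect_lt(abs(mean(b) - post_mean), 4 * post_sd / sqrt(100))
  expect_lt(abs(sd(b) - post_sd), post_sd * 0.1)
  # grid oracle built from the package's own likelihood function
  grid <- seq(post_mean - 6 * post_sd, post_mean + 6 * post_sd,
              length.out = 2001)
  lp <- dnorm(grid, m0, tau0, log = TRUE) +
    vapply(grid, function(bb) loglik_point(obs, bb + log(k)), 0)
  wdens <- exp(lp - max(lp)); wdens <- wdens / sum(wdens)
  grid_mean <- sum(grid * wdens)
  grid_sd <- sqrt(sum((grid - grid_mean)^2 * wdens))
  expect_equal(grid_mean, post_mean, tolerance = 1e-6)
  expect_equal(grid_sd, post_sd, tolerance = 1e-4)
})

test_that("minimum observations only push estimates upward", {
  sim <- tiny_world(seed = 19, n_regions = 1, countries_per_region = 2,
                    periods = c(1990L, 1995L))
  cfg <- truth_model_config(sim$truth,
                            sampler = list(chains = 1, adapt = 300,
                                           burnin = 100, iter = 600,
                                           n_leapfrog = 20), seed = 3)
  model0 <- build_model(sim$obs, sim$truth$exposure, cfg)
  post0 <- fit(model0)
  psi_med0 <- median(post0$state$Psi[, 1, 1])
  add_min <- function(value) {
    bind_observations(sim$obs, classified_observation(
      "extra_min", sim$truth$exposure$countries[1], 1990L,
      "abortion_count", bound = "minimum", value = value))
  }
  post_lo <- fit(build_model(add_min(psi_med0 * 0.2),
                             sim$truth$exposure, cfg))
  post_hi <- fit(build_model(add_min(psi_med0 * 2.5),
                             sim$truth$exposure, cfg))
  med_lo <- median(post_lo$state$Psi[, 1, 1])
  med_hi <- median(post_hi$state$Psi[, 1, 1])
  # a minimum far below the posterior leaves it essentially unchanged
  expect_lt(abs(log(med_lo / psi_med0)), 0.2)
  # a minimum above shifts the posterior upward
  expect_gt(med_hi, psi_med0 * 1.3)
})

test_that("countries with data get narrower intervals than data-free peers", {
  sim <- tiny_world(seed = 23)
  regimes <- sim$raw$regimes
  none_c <- names(regimes)[regimes == "none"][1]
  rich_c <- names(regimes)[regimes == "complete_registry"][1]
  cfg <- truth_model_config(sim$truth,
                            sampler = list(chains = 1, adapt = 300,
                                           burnin = 100, iter = 600,
                                           n_leapfrog = 20), seed = 5)
  post <- fit(build_model(sim$obs, sim$truth$exposure, cfg))
  ctry <- sim$truth$exposure$countries
  width <- function(cc) {
    lg <- log(post$state$Psi[, match(cc, ctry), ])
    mean(apply(lg, 2, function(x) diff(quantile(x, c(0.1, 0.9)))))
  }
  expect_lt(width(rich_c), width(none_c))
})

test_that("the HMC engine agrees with an independent JAGS implementation of the same density", {
  sim <- tiny_world(seed = 29, n_regions = 2, countries_per_region = 2,
                    periods = c(1990L, 1995L))
  cfg <- truth_model_config(sim$truth,
                            sampler = list(chains = 1, adapt = 500,
                                           burnin = 200, iter = 2000,
                                           n_leapfrog = 25), seed = 8)
  model <- build_model(sim$obs, sim$truth$exposure, cfg)
  post <- fit(model)
  jd <- jags_oracle_fit(model, n_adapt = 1000, n_burn = 1000,
                        n_iter = 8000, seed = 8)
  for (par in c("m_om[1]", "m_om[2]", "m_al[1]", "b_om[1]", "b_al[2]",
                "a_om[3]", "log_infl[1]", "gamma_om[1]")) {
    mh <- mean(post$draws[, par]); mj <- mean(jd[, par])
    sdh <- sd(post$draws[, par])
    expect_lt(abs(mh - mj), 0.35 * max(sdh, 0.05))
  }
})

test_that("suppressing the time-series term smooths the fitted trajectories", {
  # a world with genuine period-to-period signal in the latent surfaces
  pr_wiggly <- default_priors(); pr_wiggly$rw_sd_scale <- 0.3
  truth <- generate_world(world_config(n_regions = 1,
                                       countries_per_region = 3,
                                       priors = pr_wiggly, seed = 37))
  raw <- generate_observations(truth, obs_config(seed = 38,
                                                 abortion_obs_rate = 1))
  obs <- bind_observations(
    classify_abortion_data(raw$abortion, raw$regions_with_underreporting),
    classify_intention_data(raw$intention, raw$birth_records))
  sam <- list(chains = 1, adapt = 300, burnin = 100, iter = 500,
              n_leapfrog = 20)
  pr_tight <- pr_wiggly; pr_tight$rw_sd_scale <- 0.005
  cfg_free <- truth_model_config(truth, sampler = sam, seed = 4,
                                 priors = pr_wiggly)
  cfg_tight <- truth_model_config(truth, sampler = sam, seed = 4,
                                  priors = pr_tight)
  roughness <- function(post) {
    med <- apply(log(post$state$Psi), c(2, 3), median)
    mean(abs(diff(t(med), differences = 2)))
  }
  r_free <- roughness(fit(build_model(obs, truth$exposure, cfg_free)))
  r_tight <- roughness(fit(build_model(obs, truth$exposure, cfg_tight)))
  expect_lt(r_tight, r_free)
})

test_that("regional inflation factors are recovered from paired registry and survey data", {
  truth <- generate_world(world_config(n_regions = 1,
                                       countries_per_region = 4, seed = 43))
  raw <- generate_observations(
    truth, obs_config(seed = 44,
                      regimes = c(complete_registry = 0.5,
                                  survey_with_underreporting = 0.5,
                                  incomplete_registry = 0,
                                  aicm_setting = 0, none = 0),
                      abortion_obs_rate = 1, special_rate = 0))
  obs <- bind_observations(
    classify_abortion_data(raw$abortion, raw$regions_with_underreporting),
    classify_intention_data(raw$intention, raw$birth_records))
  cfg <- truth_model_config(truth,
                            sampler = list(chains = 1, adapt = 400,
                                           burnin = 200, iter = 800,
                                           n_leapfrog = 25), seed = 9)
  post <- fit(build_model(obs, truth$exposure, cfg))
  li <- post$draws[, "log_infl[1]"]
  truth_li <- unname(truth$params$log_infl[1])
  expect_lt(abs(median(li) - truth_li), 0.3)
  q <- quantile(li, c(0.005, 0.995))
  expect_true(truth_li >= q[1] && truth_li <= q[2])
  # the paired data sharpen the factor relative to its prior
  expect_lt(sd(li), default_priors()$infl_sd)
})
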