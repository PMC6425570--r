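# fixtures built in code: small exposure/rate surfaces and datum rows

make_exposure <- function(w, countries = paste0("C", seq_len(dim(w)[2])),
                          periods = seq(1990, by = 5,
                                        length.out = dim(w)[3]),
                          births = NULL) {
  if (is.null(births)) births <- matrix(0, dim(w)[2], dim(w)[3])
  exposure_surface(w, births, countries = countries, periods = periods)
}

uniform_surface <- function(C = 2, T = 2, w = 1000, omega = 0.1,
                            alpha = 0.3) {
  wa <- array(w, c(6, C, T))
  list(exposure = make_exposure(wa),
       rates = rate_surface(array(omega, c(6, C, T)),
                            array(alpha, c(6, C, T))))
}

random_surface <- function(C = 3, T = 2, seed = 1) {
  set.seed(seed)
  wa <- array(runif(6 * C * T, 100, 5000), c(6, C, T))
  om <- array(runif(6 * C * T, 0.01, 0.3), c(6, C, T))
  al <- array(runif(6 * C * T, 0.05, 0.6), c(6, C, T))
  list(exposure = make_exposure(wa), rates = rate_surface(om, al))
}

official_datum <- function(...) {
  d <- upaest:::blank_abortion_datum("d1", "C01", 1990L, "R1")
  d$source <- "official_statistic"
  d$method <- "registry"
  d$reported_count <- 100
  d$live_births <- 0
  over <- list(...)
  for (nm in names(over)) d[[nm]] <- over[[nm]]
  d
}

study_datum <- function(...) {
  d <- upaest:::blank_abortion_datum("d1", "C01", 1990L, "R1")
  d$source <- "published_study"
  d$method <- "womens_reports"
  d$reported_count <- 100
  over <- list(...)
  for (nm in names(over)) d[[nm]] <- over[[nm]]
  d
}

intent_datum <- function(...) {
  d <- upaest:::blank_intention_datum("i1", "C01", 1990L, "R1")
  d$percent_unintended <- 40
  d$sampling_error <- 2
  over <- list(...)
  for (nm in names(over)) d[[nm]] <- over[[nm]]
  d
}

# tiny synthetic world + classified observations, shared by inference tests
tiny_world <- function(seed = 11, n_regions = 2, countries_per_region = 3,
                       periods = default_periods()) {
  truth <- generate_world(world_config(n_regions = n_regions,
                                       countries_per_region =
                                         countries_per_region,
                                       periods = periods, seed = seed))
  raw <- generate_observations(truth, obs_config(seed = seed + 1))
  obs <- bind_observations(
    classify_abortion_data(raw$abortion, raw$regions_with_underreporting),
    classify_intention_data(raw$intention, raw$birth_records))
  list(truth = truth, raw = raw, obs = obs)
}

fast_sampler <- list(chains = 1, adapt = 200, burnin = 200, iter = 400)

make_birth_records_fixture <- function(datum_id = "i1", n = 30) {
  upaest:::make_birth_records(datum_id, n, p_mar_int = 0.6, p_all = 0.4)
}
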