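#' Observation-process configuration
#'
#' Controls how imperfect abortion and intention datums are realized from a
#' synthetic truth. Countries are assigned data regimes in proportion
#' blocks, deterministically in country order. Categorical features of each
#' datum (presence, special-population sampling, probability sampling,
#' subgroup breakdowns, microdata availability, recall windows,
#' instruments, denominators) are assigned by low-discrepancy streams
#' keyed by country, period and feature (the LMUP instrument cycles over
#' eligible surveys), so the requested rates are respected and the default
#' configuration deterministically exercises every branch of both
#' classification trees;
#' measurement noise is drawn from per-country seeded streams. Complete
#' registries report the true abortion count with noise; incomplete
#' registries report a known fraction, flagged through one of the
#' official-statistic questions (cycling over all five); surveys of women
#' report the truth divided by the regional inflation factor plus noise;
#' AICM settings decompose the truth into treated complications times a
#' multiplier with separate noises. Intention surveys realize the
#' scope/instrument/microdata/recall taxonomy.
#'
#' @param regimes Named proportions over
#'   `complete_registry`, `survey_with_underreporting`,
#'   `incomplete_registry`, `aicm_setting`, `none`; must sum to 1.
#' @param abortion_obs_rate Rate at which a country-period yields an
#'   abortion datum.
#' @param intention_obs_rate Rate at which a country-period yields an
#'   intention datum.
#' @param special_rate Rate of special-population datums (excluded by the
#'   classifier).
#' @param nonnational_rate Rate of non-national probability samples among
#'   published studies.
#' @param subgroup_rate Rate of subgroup breakdowns among women's surveys.
#' @param microdata_rate Rate of intention microdata availability.
#' @param recall_rate Rate of recall periods over one year among published
#'   intention datums.
#' @param lmup_rate Rate of London Measure of Unplanned Pregnancy
#'   instruments among all-women microdata surveys.
#' @param pregnancy_denom_rate Rate of pregnancies-denominator reporting
#'   among published intention datums.
#' @param antenatal_rate Rate of antenatal-clinic samples among
#'   pregnancies-denominator datums.
#' @param no_marital_history_rate Rate of microdata lacking a marital
#'   history (bounds computed from toy birth records).
#' @param n_birth_records Toy birth records per marital-history-less datum.
#' @param sampling_se_range Range of survey sampling SEs (percent points).
#' @param noise A [classification_config()]: its variance magnitudes are
#'   used as the generation noise, so classification error components match
#'   the generative process.
#' @param seed Mandatory integer seed.
#' @return List of class `upa_obs_config`.
#' @export
obs_config <- function(regimes = c(complete_registry = 0.2,
                                   survey_with_underreporting = 0.25,
                                   incomplete_registry = 0.2,
                                   aicm_setting = 0.2, none = 0.15),
                       abortion_obs_rate = 0.7, intention_obs_rate = 0.5,
                       special_rate = 0.08, nonnational_rate = 0.2,
                       subgroup_rate = 0.3, microdata_rate = 0.6,
                       recall_rate = 0.5, lmup_rate = 0.15,
                       pregnancy_denom_rate = 0.25, antenatal_rate = 0.5,
                       no_marital_history_rate = 0.3, n_birth_records = 40L,
                       sampling_se_range = c(1.5, 3),
                       noise = classification_config(), seed) {
  if (missing(seed)) stop("a seed is mandatory (no implicit randomness)")
  if (abs(sum(regimes) - 1) > 1e-8) stop("regime proportions must sum to 1")
  structure(as.list(environment()), class = "upa_obs_config")
}

assign_regimes <- function(regimes, n) {
  counts <- floor(regimes * n)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(regimes * n - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1L
  }
  rep(names(regimes), times = counts)
}

# low-discrepancy feature streams: equidistributed in (0,1) over the
# counter, so a rate r is hit within about 1/r consecutive counters; each
# feature (salt: a non-square integer) uses a distinct irrational slope so
# streams are mutually unaligned
golden <- function(counter, salt) {
  (counter * (sqrt(salt) %% 1)) %% 1
}

#' Generate raw abortion and intention datums from a synthetic truth
#'
#' @param truth A `upa_truth` from [generate_world()].
#' @param cfg An [obs_config()].
#' @return List: `abortion` (abortion-datum table), `intention`
#'   (intention-datum table), `birth_records` (toy birth records keyed by
#'   `datum_id`), `regimes` (country regime assignment), and
#'   `regions_with_underreporting` (regions containing a complete
#'   registry, where the survey inflation factor is estimable).
#' @export
generate_observations <- function(truth, cfg) {
  stopifnot(inherits(truth, "upa_truth"), inherits(cfg, "upa_obs_config"))
  ct <- truth$countries
  C <- nrow(ct); periods <- truth$exposure$periods
  T <- length(periods)
  regime <- assign_regimes(cfg$regimes, C)
  acc <- truth$accounts
  rlev <- sort(unique(ct$region))
  ridx <- match(ct$region, rlev)
  log_infl <- truth$params$log_infl[rlev]
  rb <- truth$params$rb[rlev]
  nz <- cfg$noise
  ab <- list(); it <- list(); br <- list()
  counters <- new.env(parent = emptyenv())
  counters$lmup <- 0L
  for (i in seq_len(C)) {
    set.seed(country_seed(cfg$seed, 5000L + i))
    for (t in seq_len(T)) {
      k <- (i - 1L) * T + t
      psi <- acc$Psi[i, t]
      B <- truth$exposure$births[i, t]
      if (regime[i] != "none" && golden(k, 7L) < cfg$abortion_obs_rate) {
        ab[[length(ab) + 1L]] <- abortion_datum_row(
          i, t, k, regime[i], psi, B, ct, periods, ridx, log_infl, nz, cfg)
      }
      if (golden(k, 10L) < cfg$intention_obs_rate) {
        gen <- intention_datum_row(i, t, k, acc, ct, periods, ridx, rb,
                                   nz, cfg, counters)
        it[[length(it) + 1L]] <- gen$datum
        if (!is.null(gen$records)) br[[length(br) + 1L]] <- gen$records
      }
    }
  }
  abortion <- do.call(rbind, ab)
  intention <- do.call(rbind, it)
  records <- if (length(br)) do.call(rbind, br) else NULL
  list(abortion = abortion, intention = intention, birth_records = records,
       regimes = stats::setNames(regime, ct$country),
       regions_with_underreporting =
         unique(ct$region[regime == "complete_registry"]))
}

blank_abortion_datum <- function(id, country, period, region) {
  data.frame(datum_id = id, country = country, period = period,
             source = NA_character_, special_population = FALSE,
             national_probability_sample = TRUE, method = NA_character_,
             subgroup_breakdown = FALSE, legal_broadly_available = TRUE,
             acknowledged_completeness = NA_real_,
             below_survey_estimate = NA, period_quality_established = FALSE,
             informal_sector_substantial = FALSE,
             implausible_per_review = FALSE, includes_spontaneous = FALSE,
             reported_count = NA_real_, live_births = NA_real_,
             metric = "count", complications_treated = NA_real_,
             total_complications = NA_real_, multiplier = NA_real_,
             legal_abortions = NA_real_, region = region,
             stringsAsFactors = FALSE)
}

abortion_datum_row <- function(i, t, k, regime, psi, B, ct, periods, ridx,
                               log_infl, nz, cfg) {
  d <- blank_abortion_datum(
    sprintf("ab_%s_%d", ct$country[i], periods[t]), ct$country[i],
    periods[t], ct$region[i])
  noise <- exp(stats::rnorm(1, 0, sqrt(nz$nonsampling_default)))
  # a statistic that includes spontaneous abortions includes an unknown
  # share of the miscarriages (and possibly stillbirths), which is why the
  # classifier treats the adjusted value as an interval endpoint, not truth
  with_spontaneous <- function(a_rep) {
    inc <- stats::runif(1, 0.3, 1) * (0.1 * a_rep + 0.2 * B)
    d$includes_spontaneous <<- TRUE
    d$live_births <<- B
    a_rep + inc
  }
  if (regime == "complete_registry") {
    d$source <- "official_statistic"; d$method <- "registry"
    a_rep <- psi * noise
    if (t %% 3L == 2L) {
      d$reported_count <- with_spontaneous(a_rep)
    } else {
      d$reported_count <- a_rep
      d$acknowledged_completeness <- stats::runif(1, 0.95, 1)
    }
  } else if (regime == "incomplete_registry") {
    d$source <- "official_statistic"; d$method <- "registry"
    frac <- stats::runif(1, 0.4, 0.8)
    d$reported_count <- frac * psi * noise
    # the below-survey deficiency is a persistent country trait (the
    # classifier flags all of that country's official years); the other
    # quality issues cycle per period
    if (i %% 4L == 2L) {
      d$below_survey_estimate <- TRUE
    } else {
      reason <- (i + t) %% 4L
      if (reason == 0L) {
        d$legal_broadly_available <- FALSE
        if (t %% 2L == 0L) {
          d$reported_count <- with_spontaneous(frac * psi * noise)
        }
      } else if (reason == 1L) {
        d$acknowledged_completeness <- stats::runif(1, 0.5, 0.85)
      } else if (reason == 2L) {
        d$informal_sector_substantial <- TRUE
      } else {
        d$implausible_per_review <- TRUE
      }
    }
  } else if (regime == "survey_with_underreporting") {
    d$source <- "published_study"; d$method <- "womens_reports"
    d$special_population <- golden(k, 11L) < cfg$special_rate
    d$national_probability_sample <- golden(k, 23L) >= cfg$nonnational_rate
    d$subgroup_breakdown <- golden(k, 37L) < cfg$subgroup_rate
    svar <- nz$nonsampling_default +
      (!d$national_probability_sample) * nz$non_probability +
      d$subgroup_breakdown * nz$subgroup
    d$reported_count <- psi / exp(log_infl[ridx[i]]) *
      exp(stats::rnorm(1, 0, sqrt(svar)))
  } else if (regime == "aicm_setting") {
    d$source <- "published_study"; d$method <- "aicm"
    d$national_probability_sample <- golden(k, 23L) < 0.3
    mult_true <- stats::runif(1, 3, 7)
    c_true <- psi / mult_true
    # study authors subtract miscarriage complications imperfectly, so the
    # treated-complications count is skewed downward and bounded above by
    # the total complications including miscarriages
    misc_c <- c_true * stats::runif(1, 0.1, 0.35)
    total <- c_true + misc_c
    est_misc <- misc_c * stats::runif(1, 0.7, 1.7)
    comp <- max(total - est_misc, 0.5 * c_true) *
      exp(stats::rnorm(1, 0, sqrt(nz$complications) / 2))
    d$complications_treated <- min(comp, total)
    d$total_complications <- total
    d$multiplier <- mult_true * exp(stats::rnorm(1, 0, sqrt(nz$multiplier)))
    if (t %% 3L == 0L) {
      d$legal_abortions <- 0.25 * psi *
        exp(stats::rnorm(1, 0, sqrt(nz$legal_count)))
    }
  } else {
    stop("unknown regime ", regime)
  }
  d
}

blank_intention_datum <- function(id, country, period, region) {
  data.frame(datum_id = id, country = country, period = period,
             special_population = FALSE, national_probability_sample = TRUE,
             microdata_available = TRUE, sampling_error = NA_real_,
             recall_over_one_year = FALSE, scope = "all_women",
             denominator = "births", antenatal_clinic_sample = FALSE,
             instrument = "traditional", lmup_planned = NA_real_,
             lmup_ambivalent = NA_real_, lmup_unwanted = NA_real_,
             marital_history_available = TRUE,
             recent_birth_restriction = FALSE,
             percent_unintended = NA_real_,
             percent_marital_unintended = NA_real_, region = region,
             stringsAsFactors = FALSE)
}

noisy_pct <- function(p_true, se_pct, extra_var, shift = 0) {
  p <- min(max(p_true, 1e-3), 1 - 1e-3)
  v_samp <- (se_pct / 100 / (p * (1 - p)))^2
  100 * stats::plogis(stats::qlogis(p) + shift +
                        stats::rnorm(1, 0, sqrt(v_samp + extra_var)))
}

intention_datum_row <- function(i, t, k, acc, ct, periods, ridx, rb, nz,
                                cfg, counters) {
  d <- blank_intention_datum(
    sprintf("in_%s_%d", ct$country[i], periods[t]), ct$country[i],
    periods[t], ct$region[i])
  d$special_population <- golden(k, 13L) < cfg$special_rate
  d$national_probability_sample <- golden(k, 29L) >= cfg$nonnational_rate
  d$microdata_available <- golden(k, 41L) < cfg$microdata_rate
  se <- stats::runif(1, cfg$sampling_se_range[1], cfg$sampling_se_range[2])
  d$sampling_error <- if (d$microdata_available || golden(k, 127L) < 0.5) {
    se
  } else NA_real_
  d$recall_over_one_year <- !d$microdata_available &&
    golden(k, 53L) < cfg$recall_rate
  scope_code <- (i + t) %% 5L
  d$scope <- if (scope_code <= 2L) "all_women" else if (scope_code == 3L) {
    "ever_married"
  } else "currently_married"
  d$recent_birth_restriction <- d$scope == "currently_married" && t %% 2L == 0L
  extra <- nz$nonsampling_default +
    if (d$national_probability_sample) 0 else nz$non_probability
  shift <- if (d$recall_over_one_year) rb[ridx[i]] else 0
  p_all <- acc$births_unintended[i, t] / acc$births[i, t]
  p_mar_int <- acc$births_marital_intended[i, t] / acc$births_marital[i, t]
  if (d$scope == "all_women") {
    if (!d$microdata_available && golden(k, 79L) < cfg$pregnancy_denom_rate) {
      d$denominator <- "pregnancies"
      d$antenatal_clinic_sample <- golden(k, 97L) < cfg$antenatal_rate
      p_tgt <- if (d$antenatal_clinic_sample) {
        p_all  # antenatal sample effectively observes births
      } else {
        acc$preg_unintended[i, t] / acc$Omega[i, t]
      }
    } else {
      p_tgt <- p_all
    }
    use_lmup <- FALSE
    if (d$microdata_available && cfg$lmup_rate > 0) {
      # cycle the instrument over eligible surveys: every ceil(1/rate)-th
      # all-women microdata survey uses the LMUP
      counters$lmup <- counters$lmup + 1L
      use_lmup <- counters$lmup %%
        max(1L, as.integer(round(1 / cfg$lmup_rate))) == 1L
    }
    if (use_lmup) {
      d$instrument <- "lmup"
      amb <- stats::runif(1, 5, 15)
      u <- noisy_pct(p_tgt, se, extra, shift) - amb * stats::runif(1)
      u <- min(max(u, 0), 100 - amb)
      d$lmup_unwanted <- u
      d$lmup_ambivalent <- amb
      d$lmup_planned <- 100 - u - amb
    } else {
      d$percent_unintended <- noisy_pct(p_tgt, se, extra, shift)
    }
    d$percent_marital_unintended <-
      100 - noisy_pct(p_mar_int, se, extra + nz$subgroup, -shift)
  } else {
    # marital-scope surveys report the marital percent unintended
    d$percent_unintended <- 100 - noisy_pct(p_mar_int, se,
                                            extra + nz$subgroup, -shift)
  }
  records <- NULL
  if (d$microdata_available && !d$special_population &&
      d$scope != "currently_married" &&
      golden(k, 113L) < cfg$no_marital_history_rate) {
    d$marital_history_available <- FALSE
    records <- make_birth_records(d$datum_id, cfg$n_birth_records,
                                  p_mar_int, p_all)
  }
  list(datum = d, records = records)
}

make_birth_records <- function(datum_id, n, p_mar_int, p_all) {
  married <- stats::runif(n) < 0.7
  in_first <- married & stats::runif(n) < 0.85
  pre_union <- !married & stats::runif(n) < 0.5
  first_union <- ifelse(married | pre_union, 2005, NA_real_)
  birth <- ifelse(pre_union, 2000, 2010)
  intended <- stats::runif(n) <
    ifelse(married, p_mar_int, max(0, p_all * 0.8))
  data.frame(datum_id = datum_id, birth_date = birth,
             first_union_date = first_union,
             currently_in_first_union = ifelse(married, in_first,
                                               ifelse(pre_union, TRUE, NA)),
             intended = intended, stringsAsFactors = FALSE)
}

#' Parameter-recovery report
#'
#' Compares a posterior (or any draw matrix with JAGS-style column names)
#' to the true parameters of the synthetic world: root-mean-square error of
#' the posterior medians, mean bias, and empirical coverage of the 80% and
#' 95% equal-tailed intervals, per parameter family.
#'
#' @param truth A `upa_truth`.
#' @param posterior A `upa_posterior`, or a draws matrix.
#' @param families Parameter families to report (default all recoverable
#'   families).
#' @return Data frame with columns `family`, `n`, `rmse`, `bias`,
#'   `coverage80`, `coverage95`.
#' @export
recovery_report <- function(truth, posterior,
                            families = c("a_om", "a_al", "m_om", "m_al",
                                         "b_om", "b_al", "gamma_om",
                                         "gamma_al", "log_infl", "rb")) {
  rd <- recovery_details(truth, posterior, families)
  rows <- lapply(split(rd, rd$family), function(x) {
    data.frame(family = x$family[1], n = nrow(x),
               rmse = sqrt(mean((x$median - x$truth)^2)),
               bias = mean(x$median - x$truth),
               coverage80 = mean(x$covered80),
               coverage95 = mean(x$covered95), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[order(match(names(rows), families))])
  rownames(out) <- NULL
  out
}

#' Per-parameter coverage indicators
#'
#' Convenience for pooling coverage across seeds: one row per parameter
#' with its truth, posterior median and interval-coverage indicators.
#'
#' @inheritParams recovery_report
#' @return Data frame with `family`, `index`, `truth`, `median`,
#'   `covered80`, `covered95`.
#' @export
recovery_details <- function(truth, posterior,
                             families = c("a_om", "a_al", "m_om", "m_al",
                                          "gamma_om", "gamma_al",
                                          "log_infl")) {
  draws <- if (inherits(posterior, "upa_posterior")) {
    posterior$draws
  } else {
    as.matrix(posterior)
  }
  p <- truth$params
  rows <- lapply(families, function(fam) {
    tv <- unname(p[[fam]])
    n <- length(tv)
    cols <- sprintf("%s[%d]", fam, seq_len(n))
    if (!all(cols %in% colnames(draws))) {
      stop("index mismatch: draws lack columns for family ", fam)
    }
    dm <- draws[, cols, drop = FALSE]
    q <- apply(dm, 2, stats::quantile, probs = c(0.025, 0.1, 0.5, 0.9, 0.975))
    data.frame(family = fam, index = seq_len(n), truth = tv,
               median = q[3, ],
               covered80 = tv >= q[2, ] & tv <= q[4, ],
               covered95 = tv >= q[1, ] & tv <= q[5, ],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
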