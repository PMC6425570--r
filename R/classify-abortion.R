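#' Classification configuration
#'
#' Default magnitudes of the additive error-variance components attached to
#' classified observations. Components are variances on the transformed
#' scale (log for abortion counts/rates, logit for percentages), which keeps
#' rates positive and makes components exchangeable across indicators. The
#' magnitudes are configuration defaults: the decision logic dictates which
#' components a datum receives, not how large they are.
#'
#' @param nonsampling_default Variance of the generic non-sampling error
#'   attached to every point estimate.
#' @param non_probability Extra variance for studies without a national
#'   probability sample.
#' @param subgroup Extra variance for datums reporting subgroup breakdowns
#'   (under-reporting may vary by subgroup), and for marital-subgroup
#'   intention observations.
#' @param multiplier Variance of the AICM multiplier error.
#' @param complications Variance of the AICM treated-complications error
#'   (right-truncated at the total complications including miscarriages).
#' @param legal_count Variance of the legal-abortion count error in the
#'   modified AICM.
#' @param completeness_cutoff Acknowledged-completeness threshold below
#'   which an official statistic is a minimum estimate (0.90).
#' @param mean_sampling_error_default Fallback sampling SE (percent points)
#'   for intention datums when no survey in the run has a known SE.
#' @return A list of class `upa_class_config`.
#' @export
classification_config <- function(nonsampling_default = 0.01,
                                  non_probability = 0.04,
                                  subgroup = 0.02,
                                  multiplier = 0.09,
                                  complications = 0.04,
                                  legal_count = 0.04,
                                  completeness_cutoff = 0.90,
                                  mean_sampling_error_default = 3) {
  structure(list(nonsampling_default = nonsampling_default,
                 non_probability = non_probability,
                 subgroup = subgroup,
                 multiplier = multiplier,
                 complications = complications,
                 legal_count = legal_count,
                 completeness_cutoff = completeness_cutoff,
                 mean_sampling_error_default = mean_sampling_error_default),
            class = "upa_class_config")
}

#' Classify one abortion datum
#'
#' Implements the abortion-data decision logic. Special-population samples
#' are excluded. Published studies gain an extra error component when they
#' lack a national probability sample, then dispatch on method: surveys of
#' women yield a point estimate linked to the regional under-reporting
#' inflation factor when the region has information on under-reporting, and
#' a minimum estimate otherwise; indirect (AICM) studies are handled by
#' [aicm_observation()]. Official statistics go through the six-question
#' sequence of [classify_official()].
#'
#' @param d One abortion datum: a list or one-row data frame with fields
#'   `datum_id`, `country`, `period`, `source` (`published_study` or
#'   `official_statistic`), `special_population`,
#'   `national_probability_sample`, `method` (`womens_reports`, `aicm`,
#'   `registry`), `subgroup_breakdown`, `legal_broadly_available`,
#'   `acknowledged_completeness` (fraction in `[0,1]`, `NA` unknown),
#'   `below_survey_estimate` (`NA` unknown), `period_quality_established`,
#'   `informal_sector_substantial`, `implausible_per_review`,
#'   `includes_spontaneous`, `reported_count`, `live_births`, `metric`
#'   (`count` or `rate`), `complications_treated`, `total_complications`,
#'   `multiplier`, `legal_abortions` (`NA` if absent), `region`.
#' @param region_has_underreporting_estimate Whether the datum's modelling
#'   region has information to estimate the survey under-reporting
#'   inflation factor (a reliable official statistic coinciding with a
#'   survey of women).
#' @param config A [classification_config()].
#' @return A one-row classified-observation data frame.
#' @export
classify_abortion_datum <- function(d,
                                    region_has_underreporting_estimate = FALSE,
                                    config = classification_config()) {
  d <- as_datum(d)
  check_abortion_datum(d)
  if (isTRUE(d$special_population)) {
    return(classified_observation(
      d$datum_id, d$country, d$period, indicator = NA, excluded = TRUE,
      exclusion_reason = "special population sample",
      region = d$region, audit = "special population sample: excluded"))
  }
  audit <- "not a special population sample"
  if (identical(d$source, "official_statistic")) {
    return(classify_official(d, config, audit = audit))
  }
  if (!identical(d$source, "published_study")) {
    stop("unclassifiable datum ", d$datum_id, ": unknown source '",
         d$source, "' (no decision branch)")
  }
  comps <- numeric(0)
  if (!isTRUE(d$national_probability_sample)) {
    comps <- c(comps, non_probability = config$non_probability)
    audit <- c(audit, "no national probability sample: extra error term")
  } else {
    audit <- c(audit, "national probability sample")
  }
  if (identical(d$method, "womens_reports")) {
    comps <- c(comps, subgroup_error(d, config))
    if (isTRUE(d$subgroup_breakdown)) {
      audit <- c(audit, "subgroup breakdown: extra error term")
    }
    if (region_has_underreporting_estimate) {
      comps <- c(comps, nonsampling_default = config$nonsampling_default)
      return(classified_observation(
        d$datum_id, d$country, d$period, indicator = abortion_indicator(d),
        bound = "point", value = d$reported_count, components = comps,
        inflation_link = "regional_inflation_factor", region = d$region,
        audit = c(audit, "women's reports; regional under-reporting estimate available: point with regional inflation factor")))
    }
    return(classified_observation(
      d$datum_id, d$country, d$period, indicator = abortion_indicator(d),
      bound = "minimum", value = d$reported_count, components = comps,
      region = d$region,
      audit = c(audit, "women's reports; no regional under-reporting estimate: minimum estimate")))
  }
  if (identical(d$method, "aicm")) {
    return(aicm_observation(d, config, components = comps, audit = audit))
  }
  stop("unclassifiable datum ", d$datum_id, ": published study with method '",
       d$method, "' (no decision branch)")
}

abortion_indicator <- function(d) {
  metric <- if (is.null(d$metric) || is.na(d$metric)) "count" else d$metric
  switch(metric, count = "abortion_count", rate = "abortion_rate",
         stop("unknown abortion metric '", metric, "'"))
}

as_datum <- function(d) {
  if (is.data.frame(d)) {
    stopifnot(nrow(d) == 1L)
    d <- as.list(d)
  }
  d
}

check_abortion_datum <- function(d) {
  cmpl <- d$acknowledged_completeness
  if (!is.null(cmpl) && !is.na(cmpl) && (cmpl < 0 || cmpl > 1)) {
    stop("acknowledged_completeness must lie in [0, 1]")
  }
  ct <- d$complications_treated; tc <- d$total_complications
  if (!is.null(ct) && !is.null(tc) && !is.na(ct) && !is.na(tc) && ct > tc) {
    stop("complications_treated exceeds total complications")
  }
  invisible(TRUE)
}

#' Classify an official abortion statistic
#'
#' Applies the six questions for official statistics in their printed
#' order; the first question that triggers fixes the classification as a
#' minimum estimate: (1) legal abortion not broadly available; (2) the
#' report acknowledges completeness below 90%; (3) the statistic falls
#' below a women's-survey estimate (which marks all of that country's
#' official years, unless period-specific quality is established); (4) a
#' sizable share of abortions occurs outside the formal health sector;
#' (5) the review of outlying data found the level or trend implausible.
#' Otherwise the datum is a point estimate with a non-sampling error term.
#' Question (6): whenever the statistic includes spontaneous abortions, the
#' reported number is revised downward via [spontaneous_adjust()]; a point
#' becomes an interval (adjusted value up to the unadjusted maximum) and a
#' minimum is lowered to the adjusted value.
#'
#' Unknown acknowledged completeness proceeds to the next question (a report
#' that does not acknowledge incompleteness is taken as claiming
#' completeness).
#'
#' @param d Abortion datum with `source = "official_statistic"`.
#' @param config A [classification_config()].
#' @param audit Audit-trail prefix.
#' @return A one-row classified-observation data frame.
#' @export
classify_official <- function(d, config = classification_config(),
                              audit = character(0)) {
  d <- as_datum(d)
  if (!identical(d$source, "official_statistic")) {
    stop("classify_official requires an official statistic")
  }
  check_abortion_datum(d)
  minimum_reason <- NULL
  cmpl <- d$acknowledged_completeness
  if (!isTRUE(d$legal_broadly_available)) {
    minimum_reason <- "legal abortion not broadly available"
  } else if (!is.na(cmpl) && cmpl < config$completeness_cutoff) {
    minimum_reason <- sprintf(
      "acknowledged completeness %.0f%% below %.0f%%",
      100 * cmpl, 100 * config$completeness_cutoff)
  } else if (isTRUE(d$below_survey_estimate) &&
             !isTRUE(d$period_quality_established)) {
    minimum_reason <- "below a women's-survey estimate"
  } else if (isTRUE(d$informal_sector_substantial)) {
    minimum_reason <- "sizable informal-sector provision"
  } else if (isTRUE(d$implausible_per_review)) {
    minimum_reason <- "implausible level or trend per review"
  }
  if (is.na(cmpl)) audit <- c(audit, "completeness unknown: treated as claimed complete")
  m <- d$reported_count
  b <- if (is.null(d$live_births) || is.na(d$live_births)) 0 else d$live_births
  if (is.null(minimum_reason)) {
    audit <- c(audit, "all official-statistic questions pass")
    if (isTRUE(d$includes_spontaneous)) {
      iv <- spontaneous_adjust(m, b)
      return(classified_observation(
        d$datum_id, d$country, d$period, indicator = abortion_indicator(d),
        bound = "interval", value = iv[["low"]], value_high = iv[["high"]],
        components = c(nonsampling_default = config$nonsampling_default),
        region = d$region,
        audit = c(audit, "includes spontaneous abortions: interval [adjusted, unadjusted]")))
    }
    return(classified_observation(
      d$datum_id, d$country, d$period, indicator = abortion_indicator(d),
      bound = "point", value = m,
      components = c(nonsampling_default = config$nonsampling_default),
      region = d$region, audit = c(audit, "point estimate with error term")))
  }
  audit <- c(audit, paste0(minimum_reason, ": minimum estimate"))
  value <- m
  if (isTRUE(d$includes_spontaneous)) {
    value <- spontaneous_adjust(m, b)[["low"]]
    audit <- c(audit, "includes spontaneous abortions: minimum revised downward")
  }
  classified_observation(
    d$datum_id, d$country, d$period, indicator = abortion_indicator(d),
    bound = "minimum", value = value, region = d$region, audit = audit)
}

#' Downward revision of a statistic that includes spontaneous abortions
#'
#' A reported number `m` of abortions that includes miscarriages satisfies
#' `m = a + (a/10 + b/5) = 1.1 a + 0.2 b`, where `a` is the number of
#' induced abortions and `b` the number of live births (the pregnancy
#' identity `pregnancies = 1.2 b + 1.1 a`). Solving for `a` gives the
#' downward-revised value `(m - 0.2 b) / 1.1`, clipped at zero; the
#' unadjusted statistic is an upper bound, so the induced-abortion number
#' lies in the interval `[(m - 0.2 b) / 1.1, m]`.
#'
#' @param m Reported abortions including spontaneous ones.
#' @param b Live births over the same population and period.
#' @return Named numeric `c(low, high)`.
#' @export
spontaneous_adjust <- function(m, b) {
  if (any(m < 0) || any(b < 0)) stop("counts must be nonnegative")
  c(low = pmax(0, (m - 0.2 * b) / 1.1), high = m)
}

#' Observation from an abortion incidence complications method study
#'
#' The AICM estimate is the number of complications treated in health
#' facilities times a survey-derived multiplier (the inverse of the
#' proportion of abortions leading to treated complications). The
#' observation carries distinct error components for the multiplier and for
#' the complications count; the complications error is asymmetric,
#' truncated on the right at the total number of complications including
#' those following miscarriages (times the multiplier). When the study is a
#' modified AICM incorporating a count of legal abortions, a third error
#' component is added and the datum becomes a minimum estimate of the
#' overall abortion incidence.
#'
#' @param d Abortion datum with `method = "aicm"` and fields
#'   `complications_treated`, `multiplier`, optionally
#'   `total_complications` and `legal_abortions`.
#' @param config A [classification_config()].
#' @param components Error components inherited from earlier steps (e.g.
#'   non-probability sampling).
#' @param audit Audit-trail prefix.
#' @return A one-row classified-observation data frame.
#' @export
aicm_observation <- function(d, config = classification_config(),
                             components = numeric(0), audit = character(0)) {
  d <- as_datum(d)
  ct <- d$complications_treated
  mult <- d$multiplier
  if (is.null(ct) || is.na(ct) || is.null(mult) || is.na(mult)) {
    stop("AICM datum ", d$datum_id, " needs complications_treated and multiplier")
  }
  check_abortion_datum(d)
  value <- ct * mult
  comps <- c(components, multiplier = config$multiplier,
             complications = config$complications)
  trunc <- NA_real_
  tc <- d$total_complications
  if (!is.null(tc) && !is.na(tc)) {
    trunc <- tc * mult
    audit <- c(audit,
               "complications error truncated at total complications x multiplier")
  }
  legal <- d$legal_abortions
  if (!is.null(legal) && !is.na(legal)) {
    comps <- c(comps, legal_count = config$legal_count)
    return(classified_observation(
      d$datum_id, d$country, d$period, indicator = abortion_indicator(d),
      bound = "minimum", value = value + legal, components = comps,
      truncation = trunc, region = d$region,
      audit = c(audit, "modified AICM with legal abortions: minimum estimate with legal-count error term")))
  }
  classified_observation(
    d$datum_id, d$country, d$period, indicator = abortion_indicator(d),
    bound = "point", value = value, components = comps, truncation = trunc,
    region = d$region,
    audit = c(audit, "AICM point estimate with multiplier and complications error terms"))
}

#' Subgroup-breakdown error component
#'
#' Datums that report the distribution of abortions by subgroup gain an
#' additional error component, acknowledging that abortion under-reporting
#' may vary by subgroup.
#'
#' @param d Abortion datum.
#' @param config A [classification_config()].
#' @return Named numeric of length 1 (`subgroup` variance) if the datum has
#'   a subgroup breakdown, else an empty numeric.
#' @export
subgroup_error <- function(d, config = classification_config()) {
  d <- as_datum(d)
  if (isTRUE(d$subgroup_breakdown)) c(subgroup = config$subgroup)
  else numeric(0)
}

#' Classify a table of abortion datums
#'
#' Applies [classify_abortion_datum()] to every row, first propagating the
#' below-survey-estimate rule: when any official statistic in a country
#' falls below a women's-survey estimate, all of that country's official
#' years are marked as minimum estimates, except periods with established
#' quality.
#'
#' @param datums Data frame of abortion datums (one per row).
#' @param regions_with_underreporting Character vector of region codes in
#'   which the under-reporting inflation factor can be estimated.
#' @param config A [classification_config()].
#' @return Classified-observation table (one row per datum).
#' @export
classify_abortion_data <- function(datums, regions_with_underreporting =
                                     character(0),
                                   config = classification_config()) {
  datums <- propagate_below_survey_flag(datums)
  rows <- lapply(seq_len(nrow(datums)), function(i) {
    d <- datums[i, , drop = FALSE]
    classify_abortion_datum(
      d, region_has_underreporting_estimate =
        d$region %in% regions_with_underreporting, config = config)
  })
  do.call(bind_observations, rows)
}

propagate_below_survey_flag <- function(datums) {
  off <- datums$source == "official_statistic"
  flagged <- unique(datums$country[off & datums$below_survey_estimate %in% TRUE])
  idx <- off & datums$country %in% flagged &
    !(datums$period_quality_established %in% TRUE)
  datums$below_survey_estimate[idx] <- TRUE
  datums
}

#' Read a table of abortion datums from delimited text
#'
#' Booleans are `true`/`false`, unknowns blank.
#'
#' @param file Path to a tab-delimited datum table.
#' @return Data frame of abortion datums.
#' @export
read_abortion_data <- function(file) {
  x <- utils::read.delim(file, sep = "\t", stringsAsFactors = FALSE,
                         na.strings = "")
  flags <- c("special_population", "national_probability_sample",
             "subgroup_breakdown", "legal_broadly_available",
             "below_survey_estimate", "period_quality_established",
             "informal_sector_substantial", "implausible_per_review",
             "includes_spontaneous")
  for (f in intersect(flags, names(x))) x[[f]] <- as.logical(x[[f]])
  x
}
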