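#' Classify one pregnancy-intention datum
#'
#' Implements the intention-data decision logic. Special-population samples
#' are excluded; non-national samples gain an extra error component. The
#' sampling error is the survey's own when microdata are available or the
#' study published it, and the mean sampling error across the run's surveys
#' otherwise. Published datums with a recall period over one year (no
#' microdata) are flagged for the regional recall-bias term estimated
#' inside the inference module. Antenatal-clinic samples are recorded
#' against the births denominator regardless of the published denominator
#' (abortion is an improbable outcome there, so treating them as pregnancy
#' data would upwardly bias the percent of pregnancies intended). Scope is
#' resolved by [marital_scope()], and the London Measure of Unplanned
#' Pregnancy by [lmup_interval()]. A non-sampling error component is always
#' appended, plus a marital-subgroup component on marital-births
#' observations.
#'
#' @param d One intention datum: list or one-row data frame with fields
#'   `datum_id`, `country`, `period`, `special_population`,
#'   `national_probability_sample`, `microdata_available`, `sampling_error`
#'   (SE in percent points, `NA` unknown), `recall_over_one_year`, `scope`
#'   (`all_women`, `ever_married`, `currently_married`), `denominator`
#'   (`births` or `pregnancies`), `antenatal_clinic_sample`, `instrument`
#'   (`traditional` or `lmup`), `lmup_planned`, `lmup_ambivalent`,
#'   `lmup_unwanted`, `marital_history_available`,
#'   `recent_birth_restriction`, `percent_unintended`,
#'   `percent_marital_unintended` (`NA` if not reported), `region`.
#' @param mean_sampling_error Mean sampling SE (percent points) across the
#'   run's surveys, used when the datum's own SE is unknown.
#' @param config A [classification_config()].
#' @param birth_records Optional data frame of toy birth records for this
#'   datum (see [marital_history_bounds()]), used when microdata lack a
#'   marital history.
#' @return Classified-observation table with one or two rows (surveys of
#'   all women inform both the all-women percent and the percent of marital
#'   births intended).
#' @export
classify_intention_datum <- function(d, mean_sampling_error,
                                     config = classification_config(),
                                     birth_records = NULL) {
  d <- as_datum(d)
  check_intention_datum(d)
  if (isTRUE(d$special_population)) {
    return(classified_observation(
      d$datum_id, d$country, d$period, indicator = NA, excluded = TRUE,
      exclusion_reason = "special population sample", region = d$region,
      audit = "special population sample: excluded"))
  }
  audit <- "not a special population sample"
  comps <- c(nonsampling_default = config$nonsampling_default)
  if (!isTRUE(d$national_probability_sample)) {
    comps <- c(comps, non_probability = config$non_probability)
    audit <- c(audit, "no national probability sample: extra error term")
  }
  microdata <- isTRUE(d$microdata_available)
  if (microdata || !is.na(d$sampling_error)) {
    se <- d$sampling_error
    audit <- c(audit, "survey's own sampling error")
  } else {
    se <- mean_sampling_error
    audit <- c(audit, "mean sampling error across surveys used")
  }
  recall <- isTRUE(d$recall_over_one_year) && !microdata
  if (recall) {
    audit <- c(audit,
               "recall over one year without microdata: regional recall-bias term")
  }
  denom <- d$denominator
  if (isTRUE(d$antenatal_clinic_sample) && identical(denom, "pregnancies")) {
    denom <- "births"
    audit <- c(audit,
               "antenatal-clinic sample: recorded against births denominator")
  }
  plan <- marital_scope(d)
  rows <- list()
  if (plan$all_women_target) {
    ind <- if (identical(denom, "pregnancies")) {
      "percent_pregnancies_unintended"
    } else {
      "percent_births_unintended"
    }
    if (plan$all_women_bound == "minimum") {
      rows <- c(rows, list(classified_observation(
        d$datum_id, d$country, d$period, indicator = ind, bound = "minimum",
        value = d$percent_unintended, components = comps, sampling_se = se,
        recall_flag = recall, region = d$region,
        audit = c(audit, plan$audit,
                  "minimum on percent unintended among all women"))))
    } else if (identical(d$instrument, "lmup")) {
      iv <- lmup_interval(d$lmup_planned, d$lmup_ambivalent, d$lmup_unwanted)
      rows <- c(rows, list(classified_observation(
        d$datum_id, d$country, d$period, indicator = ind, bound = "interval",
        value = iv[["low"]], value_high = iv[["high"]], components = comps,
        sampling_se = se, recall_flag = recall, region = d$region,
        audit = c(audit, plan$audit,
                  "LMUP instrument: interval [unwanted, unwanted + ambivalent]"))))
    } else {
      rows <- c(rows, list(classified_observation(
        d$datum_id, d$country, d$period, indicator = ind, bound = "point",
        value = d$percent_unintended, components = comps, sampling_se = se,
        recall_flag = recall, region = d$region,
        audit = c(audit, plan$audit, "point on percent unintended among all women"))))
    }
  }
  if (plan$marital_target) {
    mcomps <- c(comps, subgroup = config$subgroup)
    maudit <- c(audit, plan$audit, "marital-subgroup error term")
    pm_unint <- if (identical(d$scope, "all_women")) {
      d$percent_marital_unintended
    } else {
      d$percent_unintended
    }
    if (microdata && !isTRUE(d$marital_history_available) &&
        !is.null(birth_records) && nrow(birth_records) > 0) {
      iv <- marital_history_bounds(birth_records)
      rows <- c(rows, list(classified_observation(
        d$datum_id, d$country, d$period,
        indicator = "percent_marital_births_intended", bound = "interval",
        value = iv[["low"]], value_high = iv[["high"]], components = mcomps,
        sampling_se = se, recall_flag = recall, region = d$region,
        audit = c(maudit, "no marital history: range over ambiguous post-union births"))))
    } else if (!is.null(pm_unint) && !is.na(pm_unint)) {
      if (microdata && !isTRUE(d$marital_history_available)) {
        maudit <- c(maudit,
                    "no marital history and no birth records: point fallback")
      }
      if (identical(d$instrument, "lmup")) {
        rows <- c(rows, list(classified_observation(
          d$datum_id, d$country, d$period,
          indicator = "percent_marital_births_intended", bound = "interval",
          value = d$lmup_planned, value_high = d$lmup_planned + d$lmup_ambivalent,
          components = mcomps, sampling_se = se, recall_flag = recall,
          region = d$region,
          audit = c(maudit, "LMUP instrument: interval [planned, planned + ambivalent]"))))
      } else {
        rows <- c(rows, list(classified_observation(
          d$datum_id, d$country, d$period,
          indicator = "percent_marital_births_intended", bound = "point",
          value = 100 - pm_unint, components = mcomps, sampling_se = se,
          recall_flag = recall, region = d$region,
          audit = c(maudit, "point on percent of marital births intended"))))
      }
    }
  }
  if (!length(rows)) {
    stop("datum ", d$datum_id, " produced no observation (no decision branch)")
  }
  do.call(bind_observations, rows)
}

check_intention_datum <- function(d) {
  if (!is.null(d$percent_unintended) && !is.na(d$percent_unintended) &&
      (d$percent_unintended < 0 || d$percent_unintended > 100)) {
    stop("percent_unintended must lie in [0, 100]")
  }
  if (identical(d$instrument, "lmup")) {
    s <- d$lmup_planned + d$lmup_ambivalent + d$lmup_unwanted
    if (!is.finite(s) || abs(s - 100) > 0.5) {
      stop("LMUP percents must sum to 100")
    }
  }
  invisible(TRUE)
}

#' Interval implied by the London Measure of Unplanned Pregnancy
#'
#' The LMUP classifies conceptions as planned, ambivalent or unwanted; the
#' ambivalent category mixes pregnancies that the traditional retrospective
#' measure would call intended with ones it would call unintended. The
#' percent unintended on the traditional measure therefore lies between the
#' percent unwanted and the percent unwanted plus ambivalent (equivalently,
#' 100 minus the percent planned).
#'
#' @param planned,ambivalent,unwanted LMUP percents, summing to 100.
#' @param tol Tolerance for the sum check (percent points).
#' @return Named numeric `c(low, high)` bounding the traditional percent
#'   unintended; the interval width equals the ambivalent percent.
#' @export
lmup_interval <- function(planned, ambivalent, unwanted, tol = 0.5) {
  if (any(c(planned, ambivalent, unwanted) < 0)) {
    stop("LMUP percents must be nonnegative")
  }
  if (abs(planned + ambivalent + unwanted - 100) > tol) {
    stop("LMUP percents must sum to 100")
  }
  c(low = unwanted, high = unwanted + ambivalent)
}

#' Observation targets implied by survey scope
#'
#' Surveys of all women inform both the percent unintended among all women
#' and the percent of marital births intended. Surveys of ever-married
#' women inform the marital percent. Surveys of currently married women
#' inform the marital percent when births within the past year can be
#' identified (such surveys run in countries where divorce, particularly
#' just after a birth, is extremely unlikely); otherwise the study informs
#' the maximum percent intended among all women -- stored as a minimum on
#' the percent unintended among all women, on the assumption that the
#' percent of nonmarital births intended is no higher than the marital
#' percent.
#'
#' @param d Intention datum.
#' @return List with `all_women_target`, `all_women_bound` (`"point"` or
#'   `"minimum"`), `marital_target`, and an `audit` note.
#' @export
marital_scope <- function(d) {
  d <- as_datum(d)
  scope <- d$scope
  if (is.null(scope) || is.na(scope) ||
      !scope %in% c("all_women", "ever_married", "currently_married")) {
    stop("unknown survey scope '", scope, "'")
  }
  if (scope == "all_women") {
    list(all_women_target = TRUE, all_women_bound = "point",
         marital_target = TRUE, audit = "all women sampled")
  } else if (scope == "ever_married") {
    list(all_women_target = FALSE, all_women_bound = NA_character_,
         marital_target = TRUE, audit = "ever-married women sampled")
  } else if (isTRUE(d$recent_birth_restriction)) {
    list(all_women_target = FALSE, all_women_bound = NA_character_,
         marital_target = TRUE,
         audit = "currently married, recent births identifiable")
  } else {
    list(all_women_target = TRUE, all_women_bound = "minimum",
         marital_target = FALSE,
         audit = "currently married, older births not excludable: maximum percent intended among all women")
  }
}

#' Bounds on the percent of marital births intended without a marital history
#'
#' Birth records without a full marital history leave some births
#' ambiguous: a birth after the date of first union to a woman no longer in
#' her first union may be marital or nonmarital. Births before first union
#' (or to never-married women) are nonmarital; births after first union to
#' women still in their first union are marital. The percent of marital
#' births intended is returned as the range attained over all possible
#' assignments of the ambiguous births, whose extremes are: all ambiguous
#' intended births marital and all ambiguous unintended births nonmarital
#' (upper end), and the reverse (lower end).
#'
#' @param records Data frame with columns `birth_date`, `first_union_date`
#'   (`NA` for never-married women), `currently_in_first_union` and
#'   `intended` (logical).
#' @return Named numeric `c(low, high)` in percent; degenerate (low ==
#'   high) when no birth is ambiguous.
#' @export
marital_history_bounds <- function(records) {
  if (is.null(records) || nrow(records) == 0) {
    stop("birth records must be nonempty")
  }
  need <- c("birth_date", "first_union_date", "currently_in_first_union",
            "intended")
  if (!all(need %in% names(records))) {
    stop("birth records need columns: ", paste(need, collapse = ", "))
  }
  if (any(is.na(records$currently_in_first_union) & !is.na(records$first_union_date))) {
    stop("record missing first-union status")
  }
  never <- is.na(records$first_union_date)
  pre <- !never & records$birth_date < records$first_union_date
  marital <- !never & !pre & records$currently_in_first_union
  ambiguous <- !never & !pre & !records$currently_in_first_union
  I0 <- sum(records$intended[marital])
  N0 <- sum(marital)
  Ia <- sum(records$intended[ambiguous])
  Ua <- sum(ambiguous) - Ia
  pct <- function(i, n) if (n == 0) NA_real_ else 100 * i / n
  # extremes over all assignments of ambiguous births to marital/nonmarital
  hi <- pct(I0 + Ia, N0 + Ia)
  lo <- pct(I0, N0 + Ua)
  if (N0 == 0 && Ia + Ua == 0) stop("no marital or ambiguous births in records")
  if (is.na(hi)) hi <- lo
  if (is.na(lo)) lo <- hi
  c(low = min(lo, hi), high = max(lo, hi))
}

#' Mean sampling error across a run's intention datums
#'
#' @param datums Intention-datum table.
#' @param config A [classification_config()] supplying the fallback when no
#'   datum has a known sampling error.
#' @return Mean SE in percent points.
#' @export
mean_sampling_error <- function(datums, config = classification_config()) {
  se <- datums$sampling_error
  se <- se[!is.na(se)]
  if (length(se)) mean(se) else config$mean_sampling_error_default
}

#' Classify a table of intention datums
#'
#' @param datums Intention-datum table (one datum per row).
#' @param birth_records Optional companion table of toy birth records with a
#'   `datum_id` key.
#' @param config A [classification_config()].
#' @return Classified-observation table.
#' @export
classify_intention_data <- function(datums, birth_records = NULL,
                                    config = classification_config()) {
  mse <- mean_sampling_error(datums, config)
  rows <- lapply(seq_len(nrow(datums)), function(i) {
    d <- datums[i, , drop = FALSE]
    br <- NULL
    if (!is.null(birth_records)) {
      br <- birth_records[birth_records$datum_id == d$datum_id, , drop = FALSE]
      if (nrow(br) == 0) br <- NULL
    }
    classify_intention_datum(d, mse, config, birth_records = br)
  })
  do.call(bind_observations, rows)
}

#' Read a table of intention datums from delimited text
#'
#' @param file Path to a tab-delimited datum table.
#' @return Data frame of intention datums.
#' @export
read_intention_data <- function(file) {
  x <- utils::read.delim(file, sep = "\t", stringsAsFactors = FALSE,
                         na.strings = "")
  flags <- c("special_population", "national_probability_sample",
             "microdata_available", "recall_over_one_year",
             "antenatal_clinic_sample", "marital_history_available",
             "recent_birth_restriction")
  for (f in intersect(flags, names(x))) x[[f]] <- as.logical(x[[f]])
  x
}
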