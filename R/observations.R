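#' Classified observations
#'
#' A classified observation is one typed datum ready for the likelihood: an
#' indicator, a bound type (point, minimum, maximum or interval), a value
#' (and upper value for intervals), additive error-variance components on
#' the transformed scale (log for abortion quantities, logit for
#' percentages), an optional right-truncation, an optional link to the
#' regional under-reporting inflation factor, and an audit trail of the path
#' the datum took through the decision logic.
#'
#' @name classified_observation
NULL

obs_indicators <- function() {
  c("abortion_count", "abortion_rate", "percent_births_unintended",
    "percent_pregnancies_unintended", "percent_marital_births_intended")
}

obs_bounds <- function() c("point", "minimum", "maximum", "interval")

#' Construct a classified observation
#'
#' @param datum_id Identifier of the source datum.
#' @param country,period Country code and period start year.
#' @param indicator One of `abortion_count`, `abortion_rate`,
#'   `percent_births_unintended`, `percent_pregnancies_unintended`,
#'   `percent_marital_births_intended`.
#' @param bound One of `point`, `minimum`, `maximum`, `interval`.
#' @param value Observed value (lower endpoint for intervals), on the
#'   natural scale (counts; rates per 1,000 women-years; percents 0-100).
#' @param value_high Upper endpoint for `interval` observations.
#' @param components Named numeric vector of error-variance components on
#'   the transformed scale (e.g. `c(nonsampling_default = 0.01)`).
#' @param sampling_se Sampling standard error on the natural (percent)
#'   scale, if known; `NA` otherwise.
#' @param inflation_link `"none"` or `"regional_inflation_factor"`.
#' @param truncation Optional right-truncation point on the natural scale
#'   (AICM complications bound); `NA` if none.
#' @param recall_flag `TRUE` when the datum needs the regional recall-bias
#'   term (recall period over a year without microdata).
#' @param region Region code (may be filled later from model configuration).
#' @param excluded `TRUE` when the datum does not inform the model.
#' @param exclusion_reason Reason string when excluded.
#' @param audit Character vector of decision-path steps.
#' @return One-row data frame with the observation schema.
#' @export
classified_observation <- function(datum_id, country, period, indicator,
                                   bound = "point", value = NA_real_,
                                   value_high = NA_real_,
                                   components = numeric(0),
                                   sampling_se = NA_real_,
                                   inflation_link = "none",
                                   truncation = NA_real_,
                                   recall_flag = FALSE,
                                   region = NA_character_,
                                   excluded = FALSE,
                                   exclusion_reason = NA_character_,
                                   audit = character(0)) {
  if (!excluded) {
    if (!indicator %in% obs_indicators()) {
      stop("unknown indicator: ", indicator)
    }
    if (!bound %in% obs_bounds()) stop("unknown bound type: ", bound)
    if (bound == "interval") {
      if (is.na(value_high)) stop("interval observation needs value_high")
      if (value > value_high) stop("interval observation has value > value_high")
    }
    if (length(components) == 0 && bound == "point") {
      stop("a point observation needs at least one error component")
    }
  }
  data.frame(
    datum_id = as.character(datum_id), country = as.character(country),
    period = as.integer(period),
    indicator = if (excluded) NA_character_ else indicator,
    bound = if (excluded) NA_character_ else bound,
    value = as.numeric(value), value_high = as.numeric(value_high),
    error_components = format_components(components),
    sampling_se = as.numeric(sampling_se),
    inflation_link = inflation_link, truncation = as.numeric(truncation),
    recall_flag = isTRUE(recall_flag), region = region,
    excluded = isTRUE(excluded), exclusion_reason = exclusion_reason,
    audit = paste(audit, collapse = "; "),
    stringsAsFactors = FALSE)
}

#' @rdname classified_observation
#' @param components Named numeric vector of variance components.
#' @export
format_components <- function(components) {
  if (length(components) == 0) return("")
  if (is.null(names(components)) || any(names(components) == "")) {
    stop("error components must be named")
  }
  paste(sprintf("%s=%.10g", names(components), components), collapse = ";")
}

#' @rdname classified_observation
#' @param x Serialized component string (`"name=var;name=var"`).
#' @export
parse_components <- function(x) {
  if (is.na(x) || !nzchar(x)) return(stats::setNames(numeric(0), character(0)))
  parts <- strsplit(x, ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  stats::setNames(vapply(kv, function(p) as.numeric(p[2]), 0),
                  vapply(kv, `[[`, "", 1))
}

#' Total error variance of an observation row
#'
#' Sums the labelled variance components and, for percent indicators with a
#' known sampling standard error, the sampling variance transformed to the
#' logit scale by the delta method at the observed value.
#'
#' @param obs One row of a classified-observation table.
#' @return Total variance on the transformed scale.
#' @export
obs_total_variance <- function(obs) {
  v <- sum(parse_components(obs$error_components))
  if (!is.na(obs$sampling_se) && startsWith(obs$indicator, "percent")) {
    p <- pmin(pmax(obs$value / 100, 1e-4), 1 - 1e-4)
    se_p <- obs$sampling_se / 100
    v <- v + (se_p / (p * (1 - p)))^2
  }
  v
}

#' Bind classified observations into one table
#'
#' @param ... One-row observation data frames or tables thereof.
#' @return A single observation table.
#' @export
bind_observations <- function(...) {
  rows <- Filter(Negate(is.null), list(...))
  if (!length(rows)) return(empty_observations())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

empty_observations <- function() {
  classified_observation("x", "x", 1990L, "abortion_count", "minimum",
                         0)[0, ]
}

#' Read/write classified-observation tables
#'
#' @param x Observation table.
#' @param file Path to a tab-delimited file.
#' @return `read_observations` returns the observation table;
#'   `write_observations` returns the path invisibly.
#' @export
write_observations <- function(x, file) {
  utils::write.table(x, file, sep = "\t", row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(file)
}

#' @rdname write_observations
#' @export
read_observations <- function(file) {
  out <- utils::read.delim(file, sep = "\t", stringsAsFactors = FALSE,
                           na.strings = "")
  out$recall_flag <- as.logical(out$recall_flag)
  out$excluded <- as.logical(out$excluded)
  if (is.logical(out$error_components)) {
    out$error_components <- ifelse(is.na(out$error_components), "",
                                   as.character(out$error_components))
  }
  out$error_components[is.na(out$error_components)] <- ""
  out
}
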