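#' Exposure surface: women by group and live births by country-period
#'
#' Bundles the demographic inputs of the accounting model: counts of women
#' aged 15-49 per population group, country and five-year period, and live
#' births per country-period (UNPD-style inputs).
#'
#' @param women Numeric array with dimensions `c(6, n_countries, n_periods)`
#'   (group, country, period) of women counts, or a long data frame with
#'   columns `country`, `period_start`, `group_marital`, `group_need`,
#'   `women`.
#' @param births Numeric matrix `n_countries x n_periods` of live births
#'   (`NA` where no UNPD estimate is available), or a data frame with
#'   columns `country`, `period_start`, `live_births`.
#' @param countries Character vector of country codes. Required when `women`
#'   is an array without dimnames.
#' @param periods Integer vector of period start years (default the six
#'   periods 1990-2015).
#' @param tol Relative tolerance used by [validate_exposure()] when checking
#'   stated totals.
#' @return An object of class `upa_exposure`: a list with elements `women`
#'   (array `[6, C, T]` with dimnames), `births` (matrix `[C, T]`),
#'   `countries`, `periods`, `groups` (the [population_groups()] table).
#' @export
exposure_surface <- function(women, births, countries = NULL,
                             periods = default_periods(), tol = 1e-6) {
  groups <- population_groups()
  if (is.data.frame(women)) {
    parsed <- exposure_from_frames(women, births, periods)
    women <- parsed$women
    births <- parsed$births
    countries <- parsed$countries
  } else {
    if (length(dim(women)) != 3L || dim(women)[1] != nrow(groups)) {
      stop("`women` must be a [6, country, period] array")
    }
    if (is.null(countries)) countries <- dimnames(women)[[2]]
    if (is.null(countries)) {
      stop("`countries` must be supplied when `women` has no dimnames")
    }
    births <- as.matrix(births)
  }
  if (dim(women)[2] != length(countries) ||
      dim(women)[3] != length(periods)) {
    stop("`women` dimensions do not match countries/periods")
  }
  if (!all(dim(births) == c(length(countries), length(periods)))) {
    stop("`births` must be a country x period matrix")
  }
  dimnames(women) <- list(groups$group, countries, periods)
  dimnames(births) <- list(countries, periods)
  out <- structure(
    list(women = women, births = births, countries = countries,
         periods = as.integer(periods), groups = groups),
    class = "upa_exposure")
  validate_exposure(out, tol = tol)
  out
}

exposure_from_frames <- function(women_df, births_df, periods) {
  need <- c("country", "period_start", "group_marital", "group_need", "women")
  if (!all(need %in% names(women_df))) {
    stop("women table needs columns: ", paste(need, collapse = ", "))
  }
  needb <- c("country", "period_start", "live_births")
  if (!all(needb %in% names(births_df))) {
    stop("births table needs columns: ", paste(needb, collapse = ", "))
  }
  groups <- population_groups()
  countries <- sort(unique(women_df$country))
  women <- array(0, c(nrow(groups), length(countries), length(periods)))
  gi <- match(paste(women_df$group_marital, women_df$group_need, sep = "."),
              groups$group)
  if (anyNA(gi)) stop("unknown population group in women table")
  ci <- match(women_df$country, countries)
  ti <- match(women_df$period_start, periods)
  if (anyNA(ti)) stop("women table has a period_start outside the period grid")
  women[cbind(gi, ci, ti)] <- women_df$women
  births <- matrix(0, length(countries), length(periods))
  cb <- match(births_df$country, countries)
  if (anyNA(cb)) stop("births table has a country absent from the women table")
  tb <- match(births_df$period_start, periods)
  if (anyNA(tb)) stop("births table has a period_start outside the period grid")
  births[cbind(cb, tb)] <- births_df$live_births
  list(women = women, births = births, countries = countries)
}

#' Validate an exposure surface
#'
#' Checks nonnegativity of all counts and, when a `stated_total` attribute or
#' argument is present, that group counts sum to the stated number of women
#' of reproductive age within tolerance.
#'
#' @param x A `upa_exposure` object.
#' @param stated_total Optional country x period matrix of stated totals of
#'   women aged 15-49.
#' @param tol Relative tolerance for the stated-total check.
#' @return `x`, invisibly; stops on violation.
#' @export
validate_exposure <- function(x, stated_total = NULL, tol = 1e-6) {
  stopifnot(inherits(x, "upa_exposure"))
  if (any(x$women < 0)) stop("women counts must be nonnegative")
  if (any(x$births < 0, na.rm = TRUE)) {
    stop("live-birth counts must be nonnegative")
  }
  if (!is.null(stated_total)) {
    tot <- apply(x$women, c(2, 3), sum)
    rel <- abs(tot - stated_total) / pmax(1, stated_total)
    if (any(rel > tol)) {
      stop("group counts do not sum to the stated women totals")
    }
  }
  invisible(x)
}

#' Total women of reproductive age per country-period
#'
#' @param exposure A `upa_exposure` object.
#' @return Matrix `[country, period]` of summed group counts.
#' @export
women_total <- function(exposure) {
  apply(exposure$women, c(2, 3), sum)
}

#' Read exposure inputs from delimited text
#'
#' @param women_file Path to a delimited file with columns `country`,
#'   `period_start`, `group_marital`, `group_need`, `women`.
#' @param births_file Path to a delimited file with columns `country`,
#'   `period_start`, `live_births`.
#' @param periods Period start grid.
#' @param sep Field separator (default tab).
#' @return A `upa_exposure` object.
#' @export
read_exposure <- function(women_file, births_file,
                          periods = default_periods(), sep = "\t") {
  w <- utils::read.delim(women_file, sep = sep, stringsAsFactors = FALSE)
  b <- utils::read.delim(births_file, sep = sep, stringsAsFactors = FALSE)
  exposure_surface(w, b, periods = periods)
}

#' Write exposure inputs to delimited text
#'
#' @param exposure A `upa_exposure` object.
#' @param women_file,births_file Output paths.
#' @param sep Field separator.
#' @return Invisibly, the two paths.
#' @export
write_exposure <- function(exposure, women_file, births_file, sep = "\t") {
  g <- exposure$groups
  long <- expand.grid(group_id = g$group_id,
                      country = exposure$countries,
                      period_start = exposure$periods,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  long$group_marital <- g$marital_status[long$group_id]
  long$group_need <- g$need_status[long$group_id]
  long$women <- as.vector(exposure$women)
  utils::write.table(
    long[, c("country", "period_start", "group_marital", "group_need",
             "women")],
    women_file, sep = sep, row.names = FALSE, quote = FALSE)
  bl <- expand.grid(country = exposure$countries,
                    period_start = exposure$periods,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  bl$live_births <- as.vector(exposure$births)
  utils::write.table(bl, births_file, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(c(women_file, births_file))
}

#' Rate surface: pregnancy risk and abortion propensity per group
#'
#' @param omega Array `[6, C, T]` of pregnancy risks (pregnancies per woman
#'   per year), strictly positive.
#' @param alpha Array `[6, C, T]` of probabilities that a pregnancy ends in
#'   induced abortion, in the open interval (0, 1).
#' @param omega_max Upper plausibility bound on `omega` (default 1).
#' @return An object of class `upa_rates`.
#' @export
rate_surface <- function(omega, alpha, omega_max = 1) {
  omega <- as.array(omega)
  alpha <- as.array(alpha)
  if (!identical(dim(omega), dim(alpha))) {
    stop("omega and alpha must have identical dimensions")
  }
  if (any(!is.finite(omega)) || any(omega <= 0) || any(omega > omega_max)) {
    stop("omega must lie in (0, omega_max]")
  }
  if (any(!is.finite(alpha)) || any(alpha <= 0) || any(alpha >= 1)) {
    stop("alpha must lie strictly inside (0, 1)")
  }
  structure(list(omega = omega, alpha = alpha), class = "upa_rates")
}
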