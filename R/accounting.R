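#' Pregnancies per population group
#'
#' The expected number of pregnancies in group f, country c, period t is the
#' number of women in the group times their annual risk of pregnancy, times
#' the period width in years.
#'
#' @param exposure A `upa_exposure` object.
#' @param rates A `upa_rates` object on the same grid.
#' @param period_width Period width in years (default 5; pregnancy risk is
#'   defined per woman-year).
#' @return Array `[6, C, T]` of expected pregnancy counts.
#' @export
group_pregnancies <- function(exposure, rates, period_width = 5) {
  check_surfaces(exposure, rates)
  exposure$women * rates$omega * period_width
}

#' Induced abortions per country-period
#'
#' Sums, over population groups, women times pregnancy risk times the
#' group-specific probability that a pregnancy ends in induced abortion.
#'
#' @inheritParams group_pregnancies
#' @return Matrix `[C, T]` of expected abortion counts.
#' @export
total_abortions <- function(exposure, rates, period_width = 5) {
  check_surfaces(exposure, rates)
  psi_f <- exposure$women * rates$omega * rates$alpha * period_width
  apply(psi_f, c(2, 3), sum)
}

check_surfaces <- function(exposure, rates) {
  stopifnot(inherits(exposure, "upa_exposure"), inherits(rates, "upa_rates"))
  if (!identical(dim(exposure$women), dim(rates$omega))) {
    stop("exposure and rate surfaces have mismatched dimensions")
  }
  invisible(TRUE)
}

#' Expected miscarriages implied by abortions and live births
#'
#' Life tables of pregnancy loss by gestational age imply, on average, one
#' miscarriage (spontaneous fetal loss after five weeks of gestation,
#' including stillbirths) for every ten induced abortions and one for every
#' five live births.
#'
#' @param abortions,live_births Nonnegative counts (vectorized).
#' @return `abortions / 10 + live_births / 5`.
#' @export
miscarriages <- function(abortions, live_births) {
  if (any(abortions < 0) || any(live_births < 0)) {
    stop("abortions and live births must be nonnegative")
  }
  abortions / 10 + live_births / 5
}

#' Total pregnancies from live births and induced abortions
#'
#' The pregnancy identity: total pregnancies equal 1.2 times live births
#' plus 1.1 times induced abortions. This is exactly live births plus
#' abortions plus the miscarriages implied by [miscarriages()].
#'
#' @param live_births,abortions Nonnegative counts (vectorized).
#' @return Expected total pregnancies.
#' @export
pregnancy_identity <- function(live_births, abortions) {
  if (any(live_births < 0) || any(abortions < 0)) {
    stop("live births and abortions must be nonnegative")
  }
  1.2 * live_births + 1.1 * abortions
}

#' Full demographic accounts for a country-period grid
#'
#' Combines exposures and rates into expected pregnancies, abortions,
#' implied live births and miscarriages, per group and in total, plus the
#' intended/unintended split. Implied live births per group solve the
#' pregnancy identity exactly at group level:
#' `births_f = (Omega_f - 1.1 * Psi_f) / 1.2`, which makes the conservation
#' `Omega = births + Psi + M` hold to machine precision. Counts are
#' real-valued expected counts, not integers.
#'
#' @inheritParams group_pregnancies
#' @param intention_map Mapping from need status to intention source; see
#'   [default_intention_map()].
#' @return An object of class `upa_accounts`: a list with per-group arrays
#'   `Omega_f`, `Psi_f`, `births_f`, `misc_f` (`[6, C, T]`), country-period
#'   matrices `Omega`, `Psi`, `births`, `misc`, the intended/unintended
#'   splits `preg_intended`, `preg_unintended`, `births_intended`,
#'   `births_unintended`, abortions from unintended-source groups
#'   `Psi_unintended`, marital-birth components `births_marital`,
#'   `births_marital_intended`, and metadata (`countries`, `periods`,
#'   `period_width`, `intention`).
#' @export
pregnancy_accounts <- function(exposure, rates, period_width = 5,
                               intention_map = default_intention_map()) {
  Omega_f <- group_pregnancies(exposure, rates, period_width)
  Psi_f <- Omega_f * rates$alpha
  if (any(Psi_f > Omega_f)) stop("group abortions exceed group pregnancies")
  births_f <- (Omega_f - 1.1 * Psi_f) / 1.2
  if (any(births_f < 0)) {
    warning("implied live births negative for some group (alpha > 1/1.1); ",
            "accounts are inconsistent with the miscarriage ratios")
  }
  misc_f <- 0.1 * Psi_f + 0.2 * births_f
  intent <- group_intention(intention_map)
  unint <- intent == "unintended"
  married <- population_groups()$marital_status == "married"
  sum_groups <- function(a, keep = rep(TRUE, dim(a)[1])) {
    apply(a[keep, , , drop = FALSE], c(2, 3), sum)
  }
  structure(list(
    Omega_f = Omega_f, Psi_f = Psi_f, births_f = births_f, misc_f = misc_f,
    Omega = sum_groups(Omega_f), Psi = sum_groups(Psi_f),
    births = sum_groups(births_f), misc = sum_groups(misc_f),
    preg_intended = sum_groups(Omega_f, !unint),
    preg_unintended = sum_groups(Omega_f, unint),
    births_intended = sum_groups(births_f, !unint),
    births_unintended = sum_groups(births_f, unint),
    Psi_unintended = sum_groups(Psi_f, unint),
    misc_unintended = sum_groups(misc_f, unint),
    births_marital = sum_groups(births_f, married),
    births_marital_intended = sum_groups(births_f, married & !unint),
    countries = exposure$countries, periods = exposure$periods,
    period_width = period_width, intention = intent),
    class = "upa_accounts")
}

#' Split pregnancies and births by intention source
#'
#' @param accounts A `upa_accounts` object.
#' @param intention_map Mapping from need status to intention source; must
#'   be total over the three need statuses.
#' @return List with matrices `preg_intended`, `preg_unintended`,
#'   `births_intended`, `births_unintended`; intended + unintended equal the
#'   totals exactly.
#' @export
intention_split <- function(accounts, intention_map = default_intention_map()) {
  stopifnot(inherits(accounts, "upa_accounts"))
  intent <- group_intention(intention_map)
  unint <- intent == "unintended"
  sum_groups <- function(a, keep) apply(a[keep, , , drop = FALSE], c(2, 3), sum)
  list(preg_intended = sum_groups(accounts$Omega_f, !unint),
       preg_unintended = sum_groups(accounts$Omega_f, unint),
       births_intended = sum_groups(accounts$births_f, !unint),
       births_unintended = sum_groups(accounts$births_f, unint))
}

#' Published indicator names
#'
#' The fourteen model-based indicators reported per country/region/global and
#' period: annualized rates per 1,000 women aged 15-49, and percentages of
#' pregnancies and births by intention and outcome.
#'
#' @return Character vector of indicator names, in publication order.
#' @export
indicator_names <- function() {
  c("pregnancy_rate", "unintended_pregnancy_rate", "intended_pregnancy_rate",
    "pct_pregnancies_unintended", "pct_pregnancies_intended",
    "abortion_rate", "pct_pregnancies_abortion",
    "pct_unintended_pregnancies_abortion",
    "unintended_birth_rate", "intended_birth_rate",
    "pct_births_unintended", "pct_births_intended",
    "miscarriage_rate", "pct_pregnancies_miscarriage")
}

#' Indicator table from accounts
#'
#' Computes, for every country-period, the published indicator set: rates
#' per 1,000 women aged 15-49 per year (pregnancy, unintended and intended
#' pregnancy, abortion, unintended and intended birth, miscarriage) and
#' percentages (pregnancies unintended/intended, pregnancies ending in
#' abortion, unintended pregnancies ending in abortion, births
#' unintended/intended, pregnancies ending in miscarriage). The percent of
#' unintended pregnancies ending in abortion uses abortions from
#' unintended-source groups only, in both numerator and denominator.
#'
#' @param accounts A `upa_accounts` object.
#' @param women Country x period matrix of women aged 15-49 (all groups);
#'   strictly positive.
#' @param period_width Period width in years used to annualize (defaults to
#'   the width stored in `accounts`).
#' @return Long data frame with columns `country`, `period`, `indicator`,
#'   `value`.
#' @export
indicator_table <- function(accounts, women,
                            period_width = accounts$period_width) {
  stopifnot(inherits(accounts, "upa_accounts"))
  women <- as.matrix(women)
  if (any(women <= 0)) stop("women counts must be strictly positive")
  wy <- women * period_width       # woman-years of exposure
  per1000 <- function(x) x / wy * 1000
  pct <- function(num, den) ifelse(den > 0, 100 * num / den, NA_real_)
  vals <- list(
    pregnancy_rate = per1000(accounts$Omega),
    unintended_pregnancy_rate = per1000(accounts$preg_unintended),
    intended_pregnancy_rate = per1000(accounts$preg_intended),
    pct_pregnancies_unintended = pct(accounts$preg_unintended, accounts$Omega),
    pct_pregnancies_intended = pct(accounts$preg_intended, accounts$Omega),
    abortion_rate = per1000(accounts$Psi),
    pct_pregnancies_abortion = pct(accounts$Psi, accounts$Omega),
    pct_unintended_pregnancies_abortion =
      pct(accounts$Psi_unintended, accounts$preg_unintended),
    unintended_birth_rate = per1000(accounts$births_unintended),
    intended_birth_rate = per1000(accounts$births_intended),
    pct_births_unintended = pct(accounts$births_unintended, accounts$births),
    pct_births_intended = pct(accounts$births_intended, accounts$births),
    miscarriage_rate = per1000(accounts$misc),
    pct_pregnancies_miscarriage = pct(accounts$misc, accounts$Omega))
  grid <- expand.grid(country = accounts$countries,
                      period = accounts$periods,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(indicator_names(), function(ind) {
    cbind(grid, indicator = ind, value = as.vector(vals[[ind]]),
          stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
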