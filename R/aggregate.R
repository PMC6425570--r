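#' Aggregate posterior indicator draws to regional or global level
#'
#' Counts (pregnancies, abortions, births, miscarriages and their
#' intended/unintended components) are summed across the unit's countries
#' draw by draw, and rates and percentages are then derived from the pooled
#' counts -- never by averaging country-level rates or percentages. The
#' global aggregate equals the sum over regions in every draw.
#'
#' @param posterior A `upa_posterior`.
#' @param level `"country"`, `"region"` or `"global"`.
#' @return List with `units` (unit names), `periods`, and `draws`: a named
#'   list of arrays `[n_draws, n_units, n_periods]`, one per indicator in
#'   [indicator_names()].
#' @export
aggregate_posterior <- function(posterior,
                                level = c("country", "region", "global")) {
  level <- match.arg(level)
  st <- posterior$state
  d <- posterior$model$dims
  pw <- posterior$model$config$period_width
  members <- switch(level,
    country = stats::setNames(as.list(seq_along(d$countries)), d$countries),
    region = {
      cfg_regions <- posterior$model$config$countries
      extra <- setdiff(cfg_regions$country, d$countries)
      if (length(extra)) {
        stop("aggregation error: configured countries missing from the fit: ",
             paste(extra, collapse = ", "))
      }
      lapply(stats::setNames(nm = d$regions),
             function(r) which(d$region_idx == match(r, d$regions)))
    },
    global = list(global = seq_along(d$countries)))
  nd <- dim(st$Omega)[1]; T <- dim(st$Omega)[3]
  sum_unit <- function(a, idx) {
    apply(a[, idx, , drop = FALSE], c(1, 3), sum)
  }
  out <- lapply(indicator_names(), function(i) {
    array(NA_real_, c(nd, length(members), T))
  })
  names(out) <- indicator_names()
  for (u in seq_along(members)) {
    idx <- members[[u]]
    if (!length(idx)) stop("aggregation error: empty unit ", names(members)[u])
    Om <- sum_unit(st$Omega, idx); Ps <- sum_unit(st$Psi, idx)
    bt <- sum_unit(st$births, idx); bu <- sum_unit(st$births_unint, idx)
    pu <- sum_unit(st$preg_unint, idx); psu <- sum_unit(st$Psi_unint, idx)
    mc <- 0.1 * Ps + 0.2 * bt
    Wu <- matrix(colSums(rbind(d$W[idx, , drop = FALSE])), nd, T,
                 byrow = TRUE)
    wy <- Wu * pw
    out$pregnancy_rate[, u, ] <- Om / wy * 1000
    out$unintended_pregnancy_rate[, u, ] <- pu / wy * 1000
    out$intended_pregnancy_rate[, u, ] <- (Om - pu) / wy * 1000
    out$pct_pregnancies_unintended[, u, ] <- 100 * pu / Om
    out$pct_pregnancies_intended[, u, ] <- 100 * (Om - pu) / Om
    out$abortion_rate[, u, ] <- Ps / wy * 1000
    out$pct_pregnancies_abortion[, u, ] <- 100 * Ps / Om
    out$pct_unintended_pregnancies_abortion[, u, ] <- 100 * psu_safe(psu = psu, pu = pu)
    out$unintended_birth_rate[, u, ] <- bu / wy * 1000
    out$intended_birth_rate[, u, ] <- (bt - bu) / wy * 1000
    out$pct_births_unintended[, u, ] <- 100 * bu / bt
    out$pct_births_intended[, u, ] <- 100 * (bt - bu) / bt
    out$miscarriage_rate[, u, ] <- mc / wy * 1000
    out$pct_pregnancies_miscarriage[, u, ] <- 100 * mc / Om
  }
  list(units = names(members), periods = d$periods, draws = out,
       level = level)
}

psu_safe <- function(psu, pu) ifelse(pu > 0, psu / pu, NA_real_)

#' Posterior summary tables of the published indicators
#'
#' Formats the aggregated indicator draws into a publication-shaped table:
#' posterior median and 80% / 95% uncertainty intervals per unit, period
#' and indicator.
#'
#' @param posterior A `upa_posterior`.
#' @param level `"country"`, `"region"` or `"global"`.
#' @param suppress Character vector of units to suppress from the table
#'   (e.g. countries with no data when the run configuration requests it).
#' @return Data frame with columns `unit`, `period`, `indicator`, `point`,
#'   `lower95`, `lower80`, `upper80`, `upper95`.
#' @export
report_indicators <- function(posterior, level = "country",
                              suppress = character(0)) {
  agg <- aggregate_posterior(posterior, level)
  rows <- list()
  for (ind in indicator_names()) {
    a <- agg$draws[[ind]]
    for (u in seq_along(agg$units)) {
      if (agg$units[u] %in% suppress) next
      q <- apply(a[, u, , drop = FALSE], 3, stats::quantile,
                 probs = c(0.025, 0.1, 0.5, 0.9, 0.975), na.rm = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        unit = agg$units[u], period = agg$periods, indicator = ind,
        point = q[3, ], lower95 = q[1, ], lower80 = q[2, ],
        upper80 = q[4, ], upper95 = q[5, ], stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Posterior draws of the latent value behind one observation
#'
#' Maps an observation row to its model quantity (log abortion count or
#' rate, or logit percent) per draw, including the regional inflation
#' division and recall-bias shift the likelihood applies.
#'
#' @param posterior A `upa_posterior`.
#' @param obs_row One row of the model's observation table (as stored on
#'   `posterior$model$obs`, with resolved indices).
#' @return Numeric vector of length `n_draws` on the transformed scale.
#' @export
obs_latent_draws <- function(posterior, obs_row) {
  st <- posterior$state
  ci <- obs_row$.ci; ti <- obs_row$.ti
  lat <- switch(as.character(obs_row$.oi),
    "1" = log(st$Psi[, ci, ti]),
    "2" = log(st$Psi[, ci, ti]) -
      posterior$model$data$lograte_off[ci, ti],
    "3" = stats::qlogis(st$births_unint[, ci, ti] / st$births[, ci, ti]),
    "4" = stats::qlogis(st$preg_unint[, ci, ti] / st$Omega[, ci, ti]),
    "5" = stats::qlogis(st$births_marital_intended[, ci, ti] /
                          st$births_marital[, ci, ti]),
    stop("unknown indicator code"))
  if (identical(obs_row$inflation_link, "regional_inflation_factor")) {
    lat <- lat - st$log_infl[, obs_row$.ri]
  }
  if (obs_row$.osign != 0) {
    lat <- lat + obs_row$.osign * st$rb[, obs_row$.ri]
  }
  lat
}
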