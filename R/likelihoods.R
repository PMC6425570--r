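#' Transformed scale of an observation
#'
#' Abortion counts and rates enter the likelihood on the log scale;
#' percentages enter on the logit scale (of the proportion). Values are
#' clipped away from the boundary before transforming so that transformed
#' values stay finite.
#'
#' @param indicator Observation indicator name.
#' @param value Value on the natural scale.
#' @param clip Boundary clip: minimum count, and minimum distance (percent
#'   points) of a percentage from 0 and 100.
#' @return Value on the transformed scale.
#' @export
obs_transform <- function(indicator, value, clip = c(count = 0.5, pct = 0.1)) {
  if (startsWith(indicator, "percent")) {
    p <- pmin(pmax(value, clip[["pct"]]), 100 - clip[["pct"]]) / 100
    stats::qlogis(p)
  } else {
    log(pmax(value, clip[["count"]]))
  }
}

#' Log-likelihood contribution of a point observation
#'
#' Gaussian on the transformed scale, with variance equal to the sum of the
#' observation's error components (plus the delta-method sampling variance
#' for percentages with a known sampling SE). When the observation carries
#' a right-truncation (the AICM complications bound), the density is the
#' right-truncated Gaussian, renormalized by the probability mass below the
#' truncation point -- asymmetric in the latent value.
#'
#' @param obs One row of a classified-observation table (`bound = "point"`).
#' @param latent_value Model value on the transformed scale (vectorized).
#' @return Log-density contribution(s).
#' @export
loglik_point <- function(obs, latent_value) {
  stopifnot(identical(obs$bound, "point"))
  v <- obs_total_variance(obs)
  if (!is.finite(v) || v <= 0) {
    stop("point observation needs a positive total error variance")
  }
  y <- obs_transform(obs$indicator, obs$value)
  sd <- sqrt(v)
  ll <- stats::dnorm(y, mean = latent_value, sd = sd, log = TRUE)
  if (!is.na(obs$truncation)) {
    u <- obs_transform(obs$indicator, obs$truncation)
    ll <- ll - stats::pnorm((u - latent_value) / sd, log.p = TRUE)
  }
  ll
}

#' Log-likelihood contribution of a bound observation
#'
#' Soft-bound likelihood on the transformed scale: a minimum estimate
#' contributes `log(Phi((latent - bound) / s))` (the model value should
#' exceed the bound), a maximum the mirror image, and an interval the
#' difference of the two Phi terms -- the probability that a Gaussian
#' measurement with SD `s` centred at the latent value lands inside the
#' interval. The effective SD combines the configured softness with the
#' observation's own error-variance components (and delta-method sampling
#' variance), `s = sqrt(softness^2 + total variance)`: a noisily measured
#' bound constrains less than a precise one. Hard bounds are the joint
#' `s -> 0` limit.
#'
#' @param obs One row of a classified-observation table (`bound` one of
#'   `minimum`, `maximum`, `interval`).
#' @param latent_value Model value on the transformed scale (vectorized).
#' @param softness Base soft-bound SD on the transformed scale.
#' @return Log-probability contribution(s).
#' @export
loglik_bound <- function(obs, latent_value, softness) {
  stopifnot(obs$bound %in% c("minimum", "maximum", "interval"))
  if (!is.finite(softness) || softness <= 0) {
    stop("bound softness must be positive")
  }
  softness <- sqrt(softness^2 + obs_total_variance(obs))
  lo <- obs_transform(obs$indicator, obs$value)
  if (obs$bound == "minimum") {
    return(stats::pnorm((latent_value - lo) / softness, log.p = TRUE))
  }
  if (obs$bound == "maximum") {
    return(stats::pnorm((lo - latent_value) / softness, log.p = TRUE))
  }
  hi <- obs_transform(obs$indicator, obs$value_high)
  if (lo > hi) stop("interval observation has low > high")
  log_interval_prob((lo - latent_value) / softness,
                    (hi - latent_value) / softness)
}

# stable log(Phi(zh) - Phi(zl)) for zl < zh, accurate in both tails:
# mirrored into the upper tail when the interval lies above the latent value
log_interval_prob <- function(zl, zh) {
  out <- numeric(length(zh))
  up <- zl > 0   # both z positive: use the upper-tail representation
  if (any(up)) {
    la <- stats::pnorm(-zl[up], log.p = TRUE)
    lb <- stats::pnorm(-zh[up], log.p = TRUE)
    out[up] <- la + log1p(-pmin(exp(lb - la), 1 - 1e-16))
  }
  if (any(!up)) {
    la <- stats::pnorm(zh[!up], log.p = TRUE)
    lb <- stats::pnorm(zl[!up], log.p = TRUE)
    out[!up] <- la + log1p(-pmin(exp(lb - la), 1 - 1e-16))
  }
  out
}

#' Expected observed value under a regional inflation factor
#'
#' Surveys of women under-report abortions; the regional inflation factor
#' (at least 1 on the natural scale) is the multiplicative correction whose
#' expectation matches the region's average under-reporting. The expected
#' observed value is the latent value divided by the factor; on the log
#' scale the factor's log is subtracted from the latent value.
#'
#' @param value Latent value on the natural scale (vectorized).
#' @param factor Regional inflation factor(s), `>= 1`.
#' @return Expected observed value(s).
#' @export
apply_inflation <- function(value, factor) {
  if (any(factor < 1)) stop("inflation factors must be >= 1 on the natural scale")
  value / factor
}

#' Total observation log-likelihood at given latent values
#'
#' Dispatches every row of an observation table to [loglik_point()] or
#' [loglik_bound()]. Excluded rows contribute zero.
#'
#' @param obs Classified-observation table.
#' @param latent Numeric vector of latent values on the transformed scale,
#'   one per row of `obs`.
#' @param softness Soft-bound SD.
#' @return Sum of log-likelihood contributions.
#' @export
loglik_observations <- function(obs, latent, softness) {
  stopifnot(nrow(obs) == length(latent))
  total <- 0
  for (i in seq_len(nrow(obs))) {
    o <- obs[i, , drop = FALSE]
    if (isTRUE(o$excluded)) next
    total <- total + if (o$bound == "point") {
      loglik_point(o, latent[i])
    } else {
      loglik_bound(o, latent[i], softness)
    }
  }
  total
}
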