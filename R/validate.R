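#' Holdout validation
#'
#' Refits the model after excluding either a random subset of the
#' observations or all observations from one country, and scores the
#' held-out datums against their posterior predictive distributions. The
#' goal is to assess whether the model-based estimates are unbiased and
#' whether the uncertainty assessment is appropriate: the summary reports
#' the median prediction error (bias), the RMSE, and the empirical coverage
#' of the 80% and 95% predictive intervals, all on the transformed scale.
#' Point and interval observations are scored (intervals at their
#' midpoint); pure minimum/maximum bounds are held out but not scored.
#'
#' @param obs Classified-observation table.
#' @param exposure A `upa_exposure`.
#' @param config A [model_config()].
#' @param scheme `"random_subset"` or `"leave_country_out"`.
#' @param fraction_or_country Holdout fraction in `[0, 1)` for
#'   `random_subset`; a country code for `leave_country_out`.
#' @param seed Seed for the holdout draw and the refit.
#' @param sampler Optional sampler override passed to [fit()].
#' @return List with `metrics` (one row per scored held-out datum:
#'   `datum_id`, `indicator`, `y`, `pred_median`, `error`, `covered80`,
#'   `covered95`), `summary` (`n_held_out`, `n_scored`, `bias`, `rmse`,
#'   `coverage80`, `coverage95`), `held_out` (row indices), and the refit
#'   `posterior`.
#' @export
validate_holdout <- function(obs, exposure, config,
                             scheme = c("random_subset", "leave_country_out"),
                             fraction_or_country, seed = 1L,
                             sampler = NULL) {
  scheme <- match.arg(scheme)
  live <- which(!obs$excluded)
  if (scheme == "random_subset") {
    frac <- as.numeric(fraction_or_country)
    if (frac < 0 || frac >= 1) stop("holdout fraction must lie in [0, 1)")
    n_hold <- round(frac * length(live))
    if (n_hold == 0) {
      return(list(metrics = empty_metrics(), summary = empty_summary(),
                  held_out = integer(0), posterior = NULL))
    }
    set.seed(as.integer(seed))
    held <- sort(sample(live, n_hold))
  } else {
    held <- live[obs$country[live] == fraction_or_country]
    if (!length(held)) stop("no observations for country ",
                            fraction_or_country)
  }
  train <- obs[-held, , drop = FALSE]
  warn_emptied_groups(train, obs, config)
  if (!nrow(train[!train$excluded, , drop = FALSE])) {
    stop("holdout leaves no data to fit")
  }
  model <- build_model(train, exposure, config)
  post <- fit(model, sampler = sampler, seed = seed)
  test_model <- build_model(obs[held, , drop = FALSE], exposure, config)
  metrics <- score_holdout(post, test_model$obs, seed)
  list(metrics = metrics, summary = summarize_metrics(metrics, length(held)),
       held_out = held, posterior = post)
}

empty_metrics <- function() {
  data.frame(datum_id = character(0), indicator = character(0),
             y = numeric(0), pred_median = numeric(0), error = numeric(0),
             covered80 = logical(0), covered95 = logical(0),
             stringsAsFactors = FALSE)
}

empty_summary <- function() {
  data.frame(n_held_out = 0L, n_scored = 0L, bias = NA_real_,
             rmse = NA_real_, coverage80 = NA_real_, coverage95 = NA_real_)
}

warn_emptied_groups <- function(train, full, config) {
  grp <- function(x) {
    cc <- unique(x$country[!x$excluded])
    unique(config$countries$modeling_group[config$countries$country %in% cc])
  }
  emptied <- setdiff(grp(full), grp(train))
  if (length(emptied)) {
    warning("holdout empties modeling group(s) ",
            paste(emptied, collapse = ", "),
            "; their countries fall back to the global prior")
  }
}

score_holdout <- function(post, held_obs, seed) {
  rows <- list()
  set.seed(as.integer(seed) + 7L)
  for (i in seq_len(nrow(held_obs))) {
    o <- held_obs[i, , drop = FALSE]
    if (!o$bound %in% c("point", "interval")) next
    lat <- obs_latent_draws(post, o)
    y <- if (o$bound == "point") {
      obs_transform(o$indicator, o$value)
    } else {
      (obs_transform(o$indicator, o$value) +
         obs_transform(o$indicator, o$value_high)) / 2
    }
    v <- obs_total_variance(o)
    sd_obs <- if (is.finite(v) && v > 0) sqrt(v) else 0
    pred <- lat + stats::rnorm(length(lat), 0, sd_obs)
    q <- stats::quantile(pred, c(0.025, 0.1, 0.5, 0.9, 0.975))
    rows[[length(rows) + 1L]] <- data.frame(
      datum_id = o$datum_id, indicator = o$indicator, y = y,
      pred_median = unname(q[3]), error = unname(q[3]) - y,
      covered80 = y >= q[2] && y <= q[4],
      covered95 = y >= q[1] && y <= q[5], stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty_metrics())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

summarize_metrics <- function(metrics, n_held_out) {
  if (!nrow(metrics)) {
    s <- empty_summary(); s$n_held_out <- n_held_out; return(s)
  }
  data.frame(n_held_out = n_held_out, n_scored = nrow(metrics),
             bias = stats::median(metrics$error),
             rmse = sqrt(mean(metrics$error^2)),
             coverage80 = mean(metrics$covered80),
             coverage95 = mean(metrics$covered95))
}

#' Rank covariate subsets by holdout performance
#'
#' Fits the model under each candidate covariate subset and ranks subsets
#' by random-subset holdout RMSE, breaking ties by absolute median bias and
#' then by subset size (fewer covariates win). Collinear candidates are
#' reported with the condition number of the candidate matrix.
#'
#' @param candidates Character vector of candidate covariate names
#'   (columns of `config$covariates`).
#' @param obs,exposure,config As for [validate_holdout()].
#' @param max_size Largest subset size to consider (the empty subset --
#'   baseline model -- is always included).
#' @param fraction Holdout fraction.
#' @param seed Seed shared by every subset's holdout split, so subsets are
#'   compared on the same held-out datums.
#' @param sampler Optional sampler override.
#' @param kappa_warn Condition-number threshold for the collinearity
#'   warning.
#' @return Data frame ranked best-first, with columns `covariates`
#'   (comma-separated), `size`, `rmse`, `bias`, `coverage95`.
#' @export
select_covariates <- function(candidates, obs, exposure, config,
                              max_size = 2L, fraction = 0.2, seed = 1L,
                              sampler = NULL, kappa_warn = 30) {
  if (length(candidates)) {
    M <- do.call(cbind, lapply(candidates, function(k) {
      as.vector(config$covariates[, , k])
    }))
    if (ncol(M) > 1) {
      kp <- kappa(stats::cor(M), exact = TRUE)
      if (is.finite(kp) && kp > kappa_warn) {
        warning(sprintf("candidate covariates are collinear (condition number %.1f)", kp))
      }
    }
  }
  subsets <- list(character(0))
  for (s in seq_len(min(max_size, length(candidates)))) {
    cmb <- utils::combn(candidates, s, simplify = FALSE)
    subsets <- c(subsets, cmb)
  }
  rows <- lapply(subsets, function(sub) {
    cfg <- config
    cfg$covariate_names <- if (length(sub)) sub else character(0)
    if (!length(sub)) cfg$covariates <- NULL
    v <- validate_holdout(obs, exposure, cfg, "random_subset", fraction,
                          seed = seed, sampler = sampler)
    data.frame(covariates = paste(sub, collapse = ","),
               size = length(sub), rmse = v$summary$rmse,
               bias = v$summary$bias, coverage95 = v$summary$coverage95,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$rmse, abs(out$bias), out$size), ]
  rownames(out) <- NULL
  out
}
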