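#' Fit the hierarchical model by MCMC
#'
#' Samples the joint posterior with a Metropolis-adjusted Hamiltonian Monte
#' Carlo sampler: analytic gradients drive the leapfrog proposals, the step
#' size is tuned by dual averaging during warmup (target acceptance 0.8), a
#' diagonal mass matrix is estimated from the warmup draws, and every
#' trajectory ends with an exact Metropolis accept/reject step -- so the
#' invariant distribution is the exact posterior regardless of tuning.
#' Runs are reproducible: each chain's RNG is seeded deterministically from
#' the configuration seed, so identical settings give identical draws.
#' Convergence is assessed with the potential scale reduction factor
#' (when more than one chain is run) and effective sample sizes on the
#' hyperparameters; non-converged runs are flagged in the diagnostics,
#' never silently discarded.
#'
#' @param model A `upa_model` from [build_model()].
#' @param sampler Optional override of the sampler settings in the model
#'   configuration (`chains`, `adapt`, `burnin`, `iter`, `thin`,
#'   `n_leapfrog`). `adapt + burnin` leapfrog warmup iterations are
#'   discarded; `iter` post-warmup iterations are kept (every `thin`-th).
#' @param seed Optional override of the configuration seed.
#' @param fix Optional named list fixing parameter blocks at given values
#'   (e.g. `list(a_om = rep(0, 6))`); fixed blocks are excluded from
#'   sampling. Transformed-scale blocks use the internal names
#'   (`utau_om` = unfolded country-SD, `usig_om` = unfolded innovation SD,
#'   `linfl` = log of the log inflation factor, `usd_rb`, `zrb`, `e_om`,
#'   `e_al`).
#' @param quiet Suppress progress output.
#' @return An object of class `upa_posterior`: list with `samples` (a
#'   `coda::mcmc.list` on the reporting scale), `draws` (combined draw
#'   matrix), per-draw country-period state arrays (`state`),
#'   `diagnostics` (`rhat`, `ess`, `accept_rate`, `converged`), the
#'   `model` and the seed used.
#' @export
fit <- function(model, sampler = NULL, seed = NULL, fix = NULL,
                quiet = TRUE) {
  stopifnot(inherits(model, "upa_model"))
  sa <- model$config$sampler
  if (!is.null(sampler)) sa[names(sampler)] <- sampler
  if (is.null(sa$n_leapfrog)) sa$n_leapfrog <- 20L
  if (is.null(seed)) seed <- model$config$seed
  npar <- attr(model$pars, "n")
  fixed <- fixed_mask(model, fix)
  chains <- lapply(seq_len(sa$chains), function(ch) {
    run_hmc_chain(model, sa, seed = (as.integer(seed) * 101L + ch) %%
                    .Machine$integer.max, fixed = fixed, quiet = quiet)
  })
  report <- lapply(chains, function(ch) reporting_draws(ch$draws, model))
  samples <- coda::mcmc.list(lapply(report, coda::mcmc))
  draws <- do.call(rbind, report)
  diag <- posterior_diagnostics(samples)
  diag$accept_rate <- mean(vapply(chains, `[[`, 0, "accept_rate"))
  diag$converged <- diag$converged && diag$accept_rate > 0.2
  post <- structure(list(samples = samples, draws = draws,
                         diagnostics = diag, model = model, seed = seed),
                    class = "upa_posterior")
  post$state <- posterior_state(post)
  post
}

# Gibbs updates along the two collective directions per surface that leave
# the likelihood invariant: shifting every group effect up while shifting
# every country baseline down (optionally together with the modelling-group
# means). Along these directions the full conditional is Gaussian and
# involves only the priors, so the draw is exact.
level_gibbs <- function(theta, model, fixed) {
  d <- model$data; pr <- d$priors; px <- model$pars
  for (side in c("om", "al")) {
    ia <- px[[paste0("a_", side)]]
    ib <- px[[paste0("b_", side)]]
    im <- px[[paste0("m_", side)]]
    itau <- px[[paste0("utau_", side)]]
    if (any(fixed$mask[c(ia, ib, im)])) next
    pm <- if (side == "om") pr$group_effects_omega else
      pr$group_effects_alpha
    muw <- if (side == "om") pr$mu_world_omega else pr$mu_world_alpha
    sdw <- if (side == "om") pr$sd_world_omega else pr$sd_world_alpha
    sda <- pr$sd_group_effect
    tau <- abs(theta[itau])
    a <- theta[ia]; b <- theta[ib]; m <- theta[im]
    # move 1: a + delta, b - delta (m fixed)
    P <- length(a) / sda^2 + length(b) / tau^2
    mu <- (sum(pm - a) / sda^2 + sum(b - m[d$group]) / tau^2) / P
    delta <- stats::rnorm(1, mu, 1 / sqrt(P))
    a <- a + delta; b <- b - delta
    # move 2: a + delta, b - delta, m - delta (group residuals unchanged)
    P <- length(a) / sda^2 + length(m) / sdw^2
    mu <- (sum(pm - a) / sda^2 + sum(m - muw) / sdw^2) / P
    delta <- stats::rnorm(1, mu, 1 / sqrt(P))
    a <- a + delta; b <- b - delta; m <- m - delta
    theta[ia] <- a; theta[ib] <- b; theta[im] <- m
  }
  theta
}

fixed_mask <- function(model, fix) {
  npar <- attr(model$pars, "n")
  mask <- logical(npar)
  value <- numeric(npar)
  if (!is.null(fix)) {
    for (nm in names(fix)) {
      idx <- model$pars[[nm]]
      if (is.null(idx)) stop("unknown parameter block: ", nm)
      if (length(fix[[nm]]) != length(idx)) {
        stop("fixed block ", nm, " has wrong length")
      }
      mask[idx] <- TRUE
      value[idx] <- fix[[nm]]
    }
  }
  list(mask = mask, value = value)
}

initial_theta <- function(model) {
  d <- model$data; pr <- d$priors; px <- model$pars
  theta <- numeric(attr(px, "n"))
  theta[px$a_om] <- pr$group_effects_omega
  theta[px$a_al] <- pr$group_effects_alpha
  theta[px$m_om] <- pr$mu_world_omega
  theta[px$m_al] <- pr$mu_world_alpha
  # moment-matched country baselines: solve the births identity at the
  # prior means of the group effects and abortion propensities
  thbar <- stats::plogis(pr$group_effects_alpha + pr$mu_world_alpha)
  b0 <- rep(pr$mu_world_omega, d$C)
  if (any(!is.na(d$B))) {
    for (cc in seq_len(d$C)) {
      Bc <- d$B[cc, ]
      if (all(is.na(Bc))) next
      wbar <- rowMeans(d$w[, cc, , drop = FALSE][, 1, ])
      k <- sum(wbar * exp(pr$group_effects_omega) * (1 - thbar)) / 1.2 * d$pw
      b0[cc] <- log(mean(Bc, na.rm = TRUE) / k)
    }
  }
  theta[px$b_om] <- b0
  theta[px$b_al] <- pr$mu_world_alpha
  theta[px$utau_om] <- pr$sd_country_scale / 2
  theta[px$utau_al] <- pr$sd_country_scale / 2
  theta[px$usig_om] <- pr$rw_sd_scale / 2
  theta[px$usig_al] <- pr$rw_sd_scale / 2
  theta[px$linfl] <- pr$infl_meanlog
  theta[px$mu_rb] <- pr$recall_mu0
  theta[px$usd_rb] <- pr$recall_sd_scale / 2
  theta
}

prior_scales <- function(model) {
  d <- model$data; pr <- d$priors; px <- model$pars
  sc <- rep(1, attr(px, "n"))
  sc[px$a_om] <- pr$sd_group_effect; sc[px$a_al] <- pr$sd_group_effect
  sc[px$m_om] <- pr$sd_world_omega; sc[px$m_al] <- pr$sd_world_alpha
  # baselines are strongly data-constrained; start with a stiff guess
  sc[px$b_om] <- 0.1; sc[px$b_al] <- 0.15
  sc[px$gamma_om] <- pr$coef_sd; sc[px$gamma_al] <- pr$coef_sd
  sc[c(px$utau_om, px$utau_al)] <- pr$sd_country_scale
  sc[c(px$usig_om, px$usig_al)] <- pr$rw_sd_scale
  sc[px$linfl] <- pr$infl_sdlog
  sc[px$mu_rb] <- pr$recall_mu_sd
  sc[px$usd_rb] <- pr$recall_sd_scale
  sc
}

run_hmc_chain <- function(model, sa, seed, fixed, quiet = TRUE) {
  set.seed(seed)
  px <- model$pars
  npar <- attr(px, "n")
  free <- !fixed$mask
  theta <- initial_theta(model)
  theta[fixed$mask] <- fixed$value[fixed$mask]
  theta[free] <- theta[free] + stats::rnorm(sum(free), 0, 0.01)
  inv_mass <- prior_scales(model)^2
  n_warm <- sa$adapt + sa$burnin
  n_iter <- sa$iter
  thin <- max(sa$thin, 1L)
  L0 <- sa$n_leapfrog
  cur <- log_post_grad(theta, model)
  if (!is.finite(cur$lp)) stop("initial state has zero posterior density")
  # dual averaging (target acceptance 0.8), restarted after the mass update
  eps <- 0.05; mu_da <- log(10 * eps); Hbar <- 0; lbar_eps <- log(eps)
  gamma_da <- 0.05; t0 <- 10; kappa <- 0.75; da_it <- 0
  n_keep <- floor(n_iter / thin)
  out <- matrix(NA_real_, n_keep, npar)
  acc <- 0; kept <- 0
  warm_buf <- NULL
  buf_from <- floor(n_warm * 0.3); buf_to <- floor(n_warm * 0.85)
  if (buf_to > buf_from) warm_buf <- matrix(NA_real_, buf_to - buf_from, npar)
  total <- n_warm + n_iter
  eps0_mass <- inv_mass
  for (it in seq_len(total)) {
    pmom <- stats::rnorm(npar) / sqrt(inv_mass)
    pmom[fixed$mask] <- 0
    L <- sample.int(L0, 1) + max(1L, L0 %/% 2L)
    eps_it <- eps * stats::runif(1, 0.9, 1.1)
    prop_theta <- theta
    prop_grad <- cur$grad
    pm <- pmom + 0.5 * eps_it * prop_grad
    pm[fixed$mask] <- 0
    lp_prop <- NA_real_
    diverged <- FALSE
    for (l in seq_len(L)) {
      prop_theta <- prop_theta + eps_it * inv_mass * pm
      prop_theta[fixed$mask] <- fixed$value[fixed$mask]
      st <- log_post_grad(prop_theta, model)
      if (!is.finite(st$lp)) { diverged <- TRUE; break }
      prop_grad <- st$grad
      lp_prop <- st$lp
      if (l < L) {
        pm <- pm + eps_it * prop_grad
        pm[fixed$mask] <- 0
      }
    }
    if (!diverged) {
      pm <- pm + 0.5 * eps_it * prop_grad
      pm[fixed$mask] <- 0
      h0 <- cur$lp - 0.5 * sum(pmom^2 * inv_mass)
      h1 <- lp_prop - 0.5 * sum(pm^2 * inv_mass)
      a_prob <- min(1, exp(h1 - h0))
    } else {
      a_prob <- 0
    }
    if (stats::runif(1) < a_prob) {
      theta <- prop_theta
      cur <- list(lp = lp_prop, grad = prop_grad)
    }
    # exact Gibbs moves along the likelihood-invariant level directions
    # (a + delta, b - delta[, m - delta]): conditionals involve priors only
    newtheta <- level_gibbs(theta, model, fixed)
    if (!identical(newtheta, theta)) {
      theta <- newtheta
      cur <- log_post_grad(theta, model)
    }
    if (it <= n_warm) {
      # dual averaging
      da_it <- da_it + 1
      frac <- 1 / (da_it + t0)
      Hbar <- (1 - frac) * Hbar + frac * (0.8 - a_prob)
      leps <- mu_da - sqrt(da_it) / gamma_da * Hbar
      wt <- da_it^(-kappa)
      lbar_eps <- wt * leps + (1 - wt) * lbar_eps
      eps <- exp(leps)
      if (!is.null(warm_buf) && it > buf_from && it <= buf_to) {
        warm_buf[it - buf_from, ] <- theta
      }
      if (!is.null(warm_buf) && it == buf_to) {
        vv <- apply(warm_buf, 2, stats::var)
        ok <- is.finite(vv) & vv > 1e-10
        # regularized towards the initial guess (short, correlated window)
        inv_mass[ok & free] <- 0.85 * vv[ok & free] +
          0.15 * eps0_mass[ok & free]
        # restart step-size adaptation under the new metric
        eps <- exp(lbar_eps)
        mu_da <- log(10 * eps); Hbar <- 0; lbar_eps <- log(eps); da_it <- 0
      }
      if (it == n_warm) eps <- exp(lbar_eps)
    } else {
      acc <- acc + a_prob
      j <- it - n_warm
      if (j %% thin == 0) {
        kept <- kept + 1
        out[kept, ] <- theta
      }
    }
  }
  list(draws = out[seq_len(kept), , drop = FALSE],
       accept_rate = acc / n_iter, eps = eps, inv_mass = inv_mass)
}

# map raw draws (unconstrained scale) to the reporting parameterization
reporting_draws <- function(raw, model) {
  px <- model$pars
  d <- model$data
  C <- d$C; T <- d$T; G <- d$G; R <- d$R; K <- d$K
  nd <- nrow(raw)
  cols <- list()
  grab <- function(name, labels) {
    m <- raw[, px[[name]], drop = FALSE]
    colnames(m) <- labels
    m
  }
  idxnm <- function(nm, n) sprintf("%s[%d]", nm, seq_len(n))
  cols$a_om <- grab("a_om", idxnm("a_om", 6))
  cols$a_al <- grab("a_al", idxnm("a_al", 6))
  cols$m_om <- grab("m_om", idxnm("m_om", G))
  cols$m_al <- grab("m_al", idxnm("m_al", G))
  cols$b_om <- grab("b_om", idxnm("b_om", C))
  cols$b_al <- grab("b_al", idxnm("b_al", C))
  if (K > 0) {
    cols$gamma_om <- grab("gamma_om", idxnm("gamma_om", K))
    cols$gamma_al <- grab("gamma_al", idxnm("gamma_al", K))
  }
  tau_om <- abs(raw[, px$utau_om]); tau_al <- abs(raw[, px$utau_al])
  sig_om <- abs(raw[, px$usig_om]); sig_al <- abs(raw[, px$usig_al])
  cols$scal <- cbind(tau_om = tau_om, tau_al = tau_al,
                     sig_rw_om = sig_om, sig_rw_al = sig_al)
  if (T > 1) {
    d_node <- function(e_idx, sig, nm) {
      e <- raw[, e_idx, drop = FALSE]
      dm <- matrix(0, nd, C * T)
      for (t in 2:T) {
        lower <- (t - 2L) * C
        inc <- e[, lower + seq_len(C), drop = FALSE]
        dm[, (t - 1L) * C + seq_len(C)] <-
          dm[, (t - 2L) * C + seq_len(C)] + inc
      }
      dm <- dm * sig
      colnames(dm) <- as.vector(outer(seq_len(C), seq_len(T),
                                      function(i, j)
                                        sprintf("%s[%d,%d]", nm, i, j)))
      dm
    }
    cols$d_om <- d_node(px$e_om, sig_om, "d_om")
    cols$d_al <- d_node(px$e_al, sig_al, "d_al")
  }
  li <- exp(raw[, px$linfl, drop = FALSE])
  colnames(li) <- idxnm("log_infl", R)
  cols$log_infl <- li
  sd_rb <- abs(raw[, px$usd_rb])
  rb <- raw[, px$zrb, drop = FALSE] * sd_rb + raw[, px$mu_rb]
  colnames(rb) <- idxnm("rb", R)
  cols$rb <- rb
  cols$rbh <- cbind(mu_rb = raw[, px$mu_rb], sd_rb = sd_rb)
  do.call(cbind, cols)
}

hyper_columns <- function(cn) {
  grep("^(m_om|m_al|tau_|sig_rw|gamma_|log_infl|mu_rb|sd_rb|a_om|a_al)", cn,
       value = TRUE)
}

posterior_diagnostics <- function(samples) {
  cn <- coda::varnames(samples)
  hyp <- hyper_columns(cn)
  sub <- samples[, hyp, drop = FALSE]
  rhat <- NULL
  if (coda::nchain(samples) > 1) {
    gd <- try(coda::gelman.diag(sub, multivariate = FALSE,
                                autoburnin = FALSE), silent = TRUE)
    if (!inherits(gd, "try-error")) rhat <- gd$psrf[, 1]
  }
  ess <- try(coda::effectiveSize(sub), silent = TRUE)
  if (inherits(ess, "try-error")) ess <- NULL
  converged <- is.null(rhat) || all(is.na(rhat) | rhat < 1.1)
  list(rhat = rhat, ess = ess, converged = converged)
}

#' @export
print.upa_posterior <- function(x, ...) {
  d <- x$model$dims
  cat(sprintf("upa_posterior: %d draws (%d chains), %d countries x %d periods\n",
              nrow(x$draws), coda::nchain(x$samples),
              length(d$countries), length(d$periods)))
  cat(sprintf("  mean acceptance: %.2f\n", x$diagnostics$accept_rate))
  if (!is.null(x$diagnostics$rhat)) {
    cat(sprintf("  max Rhat: %.3f%s\n",
                max(x$diagnostics$rhat, na.rm = TRUE),
                if (x$diagnostics$converged) "" else "  [NOT CONVERGED]"))
  }
  invisible(x)
}

draw_vector <- function(draws, name, n) {
  if (n == 0) return(matrix(0, nrow(draws), 0))
  cols <- sprintf("%s[%d]", name, seq_len(n))
  if (!all(cols %in% colnames(draws))) {
    stop("monitor ", name, " missing from draws")
  }
  draws[, cols, drop = FALSE]
}

draw_matrix_node <- function(draws, name, nr, nc) {
  cols <- as.vector(outer(seq_len(nr), seq_len(nc),
                          function(i, j) sprintf("%s[%d,%d]", name, i, j)))
  if (!all(cols %in% colnames(draws))) {
    stop("monitor ", name, " missing from draws")
  }
  array(draws[, cols], c(nrow(draws), nr, nc))
}

#' Per-draw country-period state of the accounting quantities
#'
#' Reconstructs, for every posterior draw, the latent surfaces and the
#' accounting aggregates (pregnancies, abortions, implied births,
#' intended/unintended and marital components) from the sampled
#' parameters, using the same deterministic mapping as the model. The
#' accounting identities therefore hold draw by draw.
#'
#' @param posterior A `upa_posterior` (the state is computed during
#'   [fit()] and stored on the object).
#' @return List of arrays `[n_draws, C, T]`: `Omega`, `Psi`, `births`,
#'   `births_unint`, `preg_unint`, `births_marital`,
#'   `births_marital_intended`, `Psi_unint`, plus draw matrices
#'   `log_infl`, `rb` (`[n_draws, R]`).
#' @export
posterior_state <- function(posterior) {
  model <- posterior$model
  draws <- posterior$draws
  d <- model$dims
  C <- length(d$countries); T <- length(d$periods); Fg <- 6L
  nd <- nrow(draws)
  K <- length(d$covariates)
  a_om <- draw_vector(draws, "a_om", Fg)
  a_al <- draw_vector(draws, "a_al", Fg)
  b_om <- draw_vector(draws, "b_om", C)
  b_al <- draw_vector(draws, "b_al", C)
  if (T > 1) {
    d_om <- draw_matrix_node(draws, "d_om", C, T)
    d_al <- draw_matrix_node(draws, "d_al", C, T)
  } else {
    d_om <- d_al <- array(0, c(nd, C, T))
  }
  xb_om <- xb_al <- array(0, c(nd, C, T))
  if (K > 0) {
    g_om <- draw_vector(draws, "gamma_om", K)
    g_al <- draw_vector(draws, "gamma_al", K)
    for (k in seq_len(K)) {
      xk <- d$X[, , k]
      xb_om <- xb_om + outer(g_om[, k], xk)
      xb_al <- xb_al + outer(g_al[, k], xk)
    }
  }
  w <- model$data$w; pw <- model$data$pw
  gint <- group_intention()
  married <- population_groups()$marital_status == "married"
  unintv <- gint == "unintended"
  zero <- matrix(0, nd, C * T)
  acc <- list(Omega = zero, Psi = zero, births = zero, births_unint = zero,
              preg_unint = zero, births_marital = zero,
              births_marital_intended = zero, Psi_unint = zero)
  base_om <- b_om[, rep(seq_len(C), T)] + matrix(d_om + xb_om, nd)
  base_al <- b_al[, rep(seq_len(C), T)] + matrix(d_al + xb_al, nd)
  for (f in seq_len(Fg)) {
    wf <- as.vector(w[f, , ])
    Omf <- sweep(exp(base_om + a_om[, f]), 2, wf * pw, `*`)
    theta <- stats::plogis(base_al + a_al[, f])
    Psif <- Omf * theta / 1.1
    bif <- (Omf - 1.1 * Psif) / 1.2
    acc$Omega <- acc$Omega + Omf
    acc$Psi <- acc$Psi + Psif
    acc$births <- acc$births + bif
    if (unintv[f]) {
      acc$births_unint <- acc$births_unint + bif
      acc$preg_unint <- acc$preg_unint + Omf
      acc$Psi_unint <- acc$Psi_unint + Psif
    }
    if (married[f]) acc$births_marital <- acc$births_marital + bif
    if (married[f] && !unintv[f]) {
      acc$births_marital_intended <- acc$births_marital_intended + bif
    }
  }
  out <- lapply(acc, function(m) array(m, c(nd, C, T)))
  R <- length(d$regions)
  out$log_infl <- draw_vector(draws, "log_infl", R)
  out$rb <- draw_vector(draws, "rb", R)
  out
}

#' Accounts object for one posterior draw
#'
#' Rebuilds the full `upa_accounts` for a single draw by reconstituting the
#' rate surfaces and calling [pregnancy_accounts()]; useful for checking
#' conservation draw by draw.
#'
#' @param posterior A `upa_posterior`.
#' @param exposure The `upa_exposure` the model was built on.
#' @param draw Draw index.
#' @return A `upa_accounts` object.
#' @export
posterior_accounts <- function(posterior, exposure, draw = 1L) {
  model <- posterior$model
  d <- model$dims
  C <- length(d$countries); T <- length(d$periods); Fg <- 6L
  row <- posterior$draws[draw, ]
  K <- length(d$covariates)
  get <- function(name, n) unname(row[sprintf("%s[%d]", name, seq_len(n))])
  a_om <- get("a_om", Fg); a_al <- get("a_al", Fg)
  b_om <- get("b_om", C); b_al <- get("b_al", C)
  dm_om <- dm_al <- matrix(0, C, T)
  if (T > 1) {
    for (t in seq_len(T)) {
      dm_om[, t] <- unname(row[sprintf("d_om[%d,%d]", seq_len(C), t)])
      dm_al[, t] <- unname(row[sprintf("d_al[%d,%d]", seq_len(C), t)])
    }
  }
  xb_om <- xb_al <- matrix(0, C, T)
  if (K > 0) {
    g_om <- get("gamma_om", K); g_al <- get("gamma_al", K)
    for (k in seq_len(K)) {
      xb_om <- xb_om + d$X[, , k] * g_om[k]
      xb_al <- xb_al + d$X[, , k] * g_al[k]
    }
  }
  eta_om <- eta_al <- array(0, c(Fg, C, T))
  for (f in seq_len(Fg)) {
    eta_om[f, , ] <- a_om[f] + b_om + xb_om + dm_om
    eta_al[f, , ] <- a_al[f] + b_al + xb_al + dm_al
  }
  rates <- rate_surface(exp(eta_om), stats::plogis(eta_al) / 1.1,
                        omega_max = Inf)
  pregnancy_accounts(exposure, rates, model$config$period_width)
}
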