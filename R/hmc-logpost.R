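# Joint log posterior and its gradient, evaluated on the unconstrained
# parameter vector. The accounting surfaces are recomputed exactly as in
# pregnancy_accounts(): Omf = w * exp(a + u) * pw, theta = ilogit(a' + v)
# (theta = 1.1 * alpha, the non-birth share), Psi = sum_f Omf * theta/1.1,
# implied births = sum_f Omf * (1 - theta)/1.2. Group surfaces are held as
# 6 x (C*T) matrices (country-period cells in columns) so every step is a
# single vectorized operation. Gradients are analytic (backpropagated
# through the aggregates) and are verified against numerical
# differentiation in the test suite; posterior correctness does not depend
# on them because the sampler applies an exact Metropolis correction.

unpack_theta <- function(theta, md) {
  px <- md$pars
  d <- md$data
  Tm1 <- max(d$T - 1L, 0L)
  list(a_om = theta[px$a_om], a_al = theta[px$a_al],
       m_om = theta[px$m_om], m_al = theta[px$m_al],
       b_om = theta[px$b_om], b_al = theta[px$b_al],
       gamma_om = theta[px$gamma_om], gamma_al = theta[px$gamma_al],
       utau_om = theta[px$utau_om], utau_al = theta[px$utau_al],
       usig_om = theta[px$usig_om], usig_al = theta[px$usig_al],
       e_om = if (Tm1 > 0) matrix(theta[px$e_om], d$C, Tm1) else
         matrix(0, d$C, 0),
       e_al = if (Tm1 > 0) matrix(theta[px$e_al], d$C, Tm1) else
         matrix(0, d$C, 0),
       linfl = theta[px$linfl], mu_rb = theta[px$mu_rb],
       usd_rb = theta[px$usd_rb], zrb = theta[px$zrb])
}

# cumulative random walk from unit innovations: cz[, 1] = 0
cum_rw <- function(e, C, T) {
  cz <- matrix(0, C, T)
  for (t in seq_len(T)[-1]) cz[, t] <- cz[, t - 1L] + e[, t - 1L]
  cz
}

covariate_term <- function(X, gamma, C, T) {
  K <- length(gamma)
  out <- matrix(0, C, T)
  for (k in seq_len(K)) out <- out + X[, , k] * gamma[k]
  out
}

# sum val by integer group index into a vector of length n
accumulate_by <- function(val, idx, n) {
  out <- numeric(n)
  for (j in seq_along(val)) out[idx[j]] <- out[idx[j]] + val[j]
  out
}

# reverse cumulative sums over periods: ge[c, s] = sum_{t >= s+1} g[c, t]
rev_cum <- function(g, C, T) {
  if (T == 1L) return(matrix(0, C, 0L))
  acc <- matrix(0, C, T)
  acc[, T] <- g[, T]
  for (t in rev(seq_len(T - 1L))) acc[, t] <- acc[, t + 1L] + g[, t]
  acc[, 2:T, drop = FALSE]
}

log_post_grad <- function(theta, md, want_grad = TRUE) {
  d <- md$data
  p <- unpack_theta(theta, md)
  pr <- d$priors
  C <- d$C; T <- d$T; CT <- C * T
  # half-normal SDs sampled unfolded: s ~ N(0, scale), SD = |s|
  tau_om <- abs(p$utau_om); tau_al <- abs(p$utau_al)
  sig_om <- abs(p$usig_om); sig_al <- abs(p$usig_al)
  x_infl <- exp(p$linfl)                  # log inflation factor, > 0
  sd_rb <- abs(p$usd_rb)
  rb <- p$mu_rb + sd_rb * p$zrb
  cz_om <- cum_rw(p$e_om, C, T); cz_al <- cum_rw(p$e_al, C, T)
  u <- matrix(p$b_om, C, T) + covariate_term(d$X, p$gamma_om, C, T) +
    sig_om * cz_om
  v <- matrix(p$b_al, C, T) + covariate_term(d$X, p$gamma_al, C, T) +
    sig_al * cz_al
  bad <- function() list(lp = -Inf, grad = numeric(length(theta)))
  if (any(!is.finite(u)) || any(!is.finite(v)) || any(abs(u) > 50)) {
    return(bad())
  }
  # group surfaces as 6 x CT matrices (columns: country fastest, then period)
  EUv <- as.vector(exp(u)) * d$pw
  Ea <- exp(p$a_om)
  Omm <- d$wmat * outer(Ea, EUv)
  Thm <- stats::plogis(outer(p$a_al, as.vector(v), "+"))
  OmTh <- Omm * Thm
  Om1Th <- Omm - OmTh
  U6 <- d$unint; M6 <- d$married; MI6 <- d$married_intended
  S1 <- .colSums(OmTh, 6L, CT); S0 <- .colSums(Om1Th, 6L, CT)
  SO <- .colSums(Omm, 6L, CT)
  S0U <- .colSums(U6 * Om1Th, 6L, CT)
  SOU <- .colSums(U6 * Omm, 6L, CT)
  S0M <- .colSums(M6 * Om1Th, 6L, CT)
  S0MI <- .colSums(MI6 * Om1Th, 6L, CT)
  Psi <- S1 / 1.1; btot <- S0 / 1.2; Omega <- SO
  bu <- S0U / 1.2; pu <- SOU; bm <- S0M / 1.2; bmi <- S0MI / 1.2
  if (any(Psi <= 0) || any(btot <= 0) || any(!is.finite(Psi))) return(bad())
  lp <- 0
  gbtot <- gPsi <- gbu <- gpu <- gOmega <- gbm <- gbmi <- numeric(CT)
  # births likelihood
  bmask <- d$bmask
  if (any(bmask)) {
    lp <- lp + sum(stats::dnorm(d$Bv[bmask], btot[bmask], d$sdBv[bmask],
                                log = TRUE))
    gbtot[bmask] <- gbtot[bmask] +
      (d$Bv[bmask] - btot[bmask]) / d$sdBv[bmask]^2
  }
  # observation likelihood
  od <- md$obsdat
  gx <- numeric(d$R); grb <- numeric(d$R)
  if (od$n > 0) {
    lin <- od$lin_idx
    qv <- numeric(od$n)
    i1 <- od$i1; i2 <- od$i2; i3 <- od$i3; i4 <- od$i4; i5 <- od$i5
    lPsi <- log(Psi)
    qv[i1] <- lPsi[lin[i1]]
    qv[i2] <- lPsi[lin[i2]] - d$lograte_off_v[lin[i2]]
    if (any(i3)) qv[i3] <- log(bu[lin[i3]]) - log(btot[lin[i3]] - bu[lin[i3]])
    if (any(i4)) qv[i4] <- log(pu[lin[i4]]) - log(Omega[lin[i4]] - pu[lin[i4]])
    if (any(i5)) qv[i5] <- log(bmi[lin[i5]]) - log(bm[lin[i5]] - bmi[lin[i5]])
    if (any(!is.finite(qv))) return(bad())
    lat <- qv - od$infl_num * x_infl[od$ri] + od$osign * rb[od$ri]
    ll <- dlat <- numeric(od$n)
    mills <- function(z) exp(stats::dnorm(z, log = TRUE) -
                               stats::pnorm(z, log.p = TRUE))
    ip <- od$ip; itp <- od$itp; imn <- od$imn; imx <- od$imx; iiv <- od$iiv
    if (any(ip)) {
      vv <- od$vtot[ip]
      ll[ip] <- stats::dnorm(od$y[ip], lat[ip], sqrt(vv), log = TRUE)
      dlat[ip] <- (od$y[ip] - lat[ip]) / vv
    }
    if (any(itp)) {
      vv <- od$vtot[itp]; sdv <- sqrt(vv)
      z <- (od$utr[itp] - lat[itp]) / sdv
      ll[itp] <- stats::dnorm(od$y[itp], lat[itp], sdv, log = TRUE) -
        stats::pnorm(z, log.p = TRUE)
      dlat[itp] <- (od$y[itp] - lat[itp]) / vv + mills(z) / sdv
    }
    if (any(imn)) {
      sm <- od$seff[imn]
      z <- (lat[imn] - od$y[imn]) / sm
      ll[imn] <- stats::pnorm(z, log.p = TRUE)
      dlat[imn] <- mills(z) / sm
    }
    if (any(imx)) {
      sm <- od$seff[imx]
      z <- (od$y[imx] - lat[imx]) / sm
      ll[imx] <- stats::pnorm(z, log.p = TRUE)
      dlat[imx] <- -mills(z) / sm
    }
    if (any(iiv)) {
      sm <- od$seff[iiv]
      zh <- (od$yhi[iiv] - lat[iiv]) / sm
      zl <- (od$y[iiv] - lat[iiv]) / sm
      liv <- log_interval_prob(zl, zh)
      ll[iiv] <- liv
      # d liv / d lat = (phi(zl) - phi(zh)) / (P * s), via logs for the tails
      ldl <- stats::dnorm(zl, log = TRUE)
      ldh <- stats::dnorm(zh, log = TRUE)
      hi_side <- ldl >= ldh
      lgap <- -abs(ldl - ldh)
      mag <- exp(pmax(ldl, ldh) - liv +
                   log1p(-pmin(exp(lgap), 1 - 1e-16)))
      dlat[iiv] <- ifelse(hi_side, mag, -mag) / sm
    }
    lp <- lp + sum(ll)
    if (!is.finite(lp)) return(bad())
    if (want_grad) {
      # latent-side adjustments
      gx <- accumulate_by(-dlat[od$infl], od$ri[od$infl], d$R)
      grb <- accumulate_by(od$osign * dlat, od$ri, d$R)
      add_ct <- function(vec, val, sub) {
        if (!any(sub)) return(vec)
        vec + accumulate_by(val[sub], lin[sub], CT)
      }
      gPsi <- add_ct(gPsi, dlat / Psi[lin], i1 | i2)
      if (any(i3)) {
        den <- btot[lin] - bu[lin]
        gbu <- add_ct(gbu, dlat * (1 / bu[lin] + 1 / den), i3)
        gbtot <- add_ct(gbtot, -dlat / den, i3)
      }
      if (any(i4)) {
        den <- Omega[lin] - pu[lin]
        gpu <- add_ct(gpu, dlat * (1 / pu[lin] + 1 / den), i4)
        gOmega <- add_ct(gOmega, -dlat / den, i4)
      }
      if (any(i5)) {
        den <- bm[lin] - bmi[lin]
        gbmi <- add_ct(gbmi, dlat * (1 / bmi[lin] + 1 / den), i5)
        gbm <- add_ct(gbm, -dlat / den, i5)
      }
    }
  }
  # priors that do not involve the surfaces
  lp <- lp + sum(stats::dnorm(p$a_om, pr$group_effects_omega,
                              pr$sd_group_effect, log = TRUE)) +
    sum(stats::dnorm(p$a_al, pr$group_effects_alpha, pr$sd_group_effect,
                     log = TRUE)) +
    sum(stats::dnorm(p$m_om, pr$mu_world_omega, pr$sd_world_omega,
                     log = TRUE)) +
    sum(stats::dnorm(p$m_al, pr$mu_world_alpha, pr$sd_world_alpha,
                     log = TRUE)) +
    sum(stats::dnorm(p$b_om, p$m_om[d$group], tau_om, log = TRUE)) +
    sum(stats::dnorm(p$b_al, p$m_al[d$group], tau_al, log = TRUE)) +
    stats::dnorm(p$utau_om, 0, pr$sd_country_scale, log = TRUE) +
    stats::dnorm(p$utau_al, 0, pr$sd_country_scale, log = TRUE) +
    stats::dnorm(p$usig_om, 0, pr$rw_sd_scale, log = TRUE) +
    stats::dnorm(p$usig_al, 0, pr$rw_sd_scale, log = TRUE) +
    sum(stats::dnorm(p$gamma_om, 0, pr$coef_sd, log = TRUE)) +
    sum(stats::dnorm(p$gamma_al, 0, pr$coef_sd, log = TRUE)) -
    0.5 * sum(p$e_om^2) - 0.5 * sum(p$e_al^2) +
    sum(stats::dnorm(p$linfl, pr$infl_meanlog, pr$infl_sdlog, log = TRUE)) +
    stats::dnorm(p$mu_rb, pr$recall_mu0, pr$recall_mu_sd, log = TRUE) +
    stats::dnorm(p$usd_rb, 0, pr$recall_sd_scale, log = TRUE) -
    0.5 * sum(p$zrb^2)
  if (!is.finite(lp)) return(bad())
  if (!want_grad) return(list(lp = lp, grad = NULL))
  # backprop through the aggregates; rx() spreads a CT vector over rows
  rx <- function(x) rep(x, each = 6L)
  gS1 <- gPsi / 1.1
  gS0 <- gbtot / 1.2
  gS0U <- gbu / 1.2; gS0M <- gbm / 1.2; gS0MI <- gbmi / 1.2
  coefOm <- rx(gS1) * Thm + (rx(gS0) + U6 * rx(gS0U) + M6 * rx(gS0M) +
                               MI6 * rx(gS0MI)) * (1 - Thm) +
    rx(gOmega) + U6 * rx(gpu)
  coefTh <- rx(gS1 - gS0) - U6 * rx(gS0U) - M6 * rx(gS0M) -
    MI6 * rx(gS0MI)
  gOmf <- coefOm * Omm
  gthf <- coefTh * Omm * Thm * (1 - Thm)
  ga_om <- .rowSums(gOmf, 6L, CT)
  ga_al <- .rowSums(gthf, 6L, CT)
  gu <- matrix(.colSums(gOmf, 6L, CT), C, T)
  gv <- matrix(.colSums(gthf, 6L, CT), C, T)
  grad <- numeric(length(theta))
  px <- md$pars
  # level backprop, omega side
  gb_om <- rowSums(gu)
  gG_om <- vapply(seq_len(d$K), function(k) sum(gu * d$X[, , k]), 0)
  gsig_om_lik <- sum(gu * cz_om)
  ge_om <- rev_cum(gu * sig_om, C, T)
  # alpha side
  gb_al <- rowSums(gv)
  gG_al <- vapply(seq_len(d$K), function(k) sum(gv * d$X[, , k]), 0)
  gsig_al_lik <- sum(gv * cz_al)
  ge_al <- rev_cum(gv * sig_al, C, T)
  # priors
  grad[px$a_om] <- ga_om - (p$a_om - pr$group_effects_omega) /
    pr$sd_group_effect^2
  grad[px$a_al] <- ga_al - (p$a_al - pr$group_effects_alpha) /
    pr$sd_group_effect^2
  res_om <- p$b_om - p$m_om[d$group]
  res_al <- p$b_al - p$m_al[d$group]
  grad[px$b_om] <- gb_om - res_om / tau_om^2
  grad[px$b_al] <- gb_al - res_al / tau_al^2
  grad[px$m_om] <- accumulate_by(res_om / tau_om^2, d$group, d$G) -
    (p$m_om - pr$mu_world_omega) / pr$sd_world_omega^2
  grad[px$m_al] <- accumulate_by(res_al / tau_al^2, d$group, d$G) -
    (p$m_al - pr$mu_world_alpha) / pr$sd_world_alpha^2
  if (d$K > 0) {
    grad[px$gamma_om] <- gG_om - p$gamma_om / pr$coef_sd^2
    grad[px$gamma_al] <- gG_al - p$gamma_al / pr$coef_sd^2
  }
  gtau_om <- sum(-1 / tau_om + res_om^2 / tau_om^3)
  gtau_al <- sum(-1 / tau_al + res_al^2 / tau_al^3)
  grad[px$utau_om] <- gtau_om * sign(p$utau_om) -
    p$utau_om / pr$sd_country_scale^2
  grad[px$utau_al] <- gtau_al * sign(p$utau_al) -
    p$utau_al / pr$sd_country_scale^2
  grad[px$usig_om] <- gsig_om_lik * sign(p$usig_om) -
    p$usig_om / pr$rw_sd_scale^2
  grad[px$usig_al] <- gsig_al_lik * sign(p$usig_al) -
    p$usig_al / pr$rw_sd_scale^2
  if (T > 1) {
    grad[px$e_om] <- as.vector(ge_om) - p$e_om
    grad[px$e_al] <- as.vector(ge_al) - p$e_al
  }
  grad[px$linfl] <- gx * x_infl -
    (p$linfl - pr$infl_meanlog) / pr$infl_sdlog^2
  grad[px$mu_rb] <- sum(grb) -
    (p$mu_rb - pr$recall_mu0) / pr$recall_mu_sd^2
  grad[px$usd_rb] <- sum(grb * p$zrb) * sign(p$usd_rb) -
    p$usd_rb / pr$recall_sd_scale^2
  grad[px$zrb] <- grb * sd_rb - p$zrb
  list(lp = lp, grad = grad)
}
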