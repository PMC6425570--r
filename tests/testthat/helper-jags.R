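# Independent cross-engine oracle: the same joint density written in JAGS
# (slice/Gibbs sampling), used to validate the package's HMC engine on
# small models where both samplers mix well.

jags_oracle_code <- function(model) {
  d <- model$data
  od <- model$obsdat
  K <- d$K; T <- d$T
  types <- od$type
  surface <- function(sfx) {
    paste(c(
      sprintf("  for (f in 1:F) { a_%s[f] ~ dnorm(pm_a_%s[f], prec_a) }",
              sfx, sfx),
      sprintf("  for (g in 1:G) { m_%s[g] ~ dnorm(mu_world_%s, prec_world_%s) }",
              sfx, sfx, sfx),
      sprintf("  tau_%s ~ dnorm(0, prec_tau_scale) T(0,)", sfx),
      sprintf("  for (c in 1:C) { b_%s[c] ~ dnorm(m_%s[group[c]], 1/(tau_%s*tau_%s)) }",
              sfx, sfx, sfx, sfx),
      if (K > 0) sprintf("  for (k in 1:K) { gamma_%s[k] ~ dnorm(0, prec_coef) }", sfx),
      sprintf("  sig_rw_%s ~ dnorm(0, prec_rw_scale) T(0,)", sfx),
      if (T > 1) sprintf(paste0(
        "  for (c in 1:C) {\n",
        "    d_%s[c,1] <- 0\n",
        "    for (t in 2:T) { d_%s[c,t] ~ dnorm(d_%s[c,t-1], 1/(sig_rw_%s*sig_rw_%s)) }\n",
        "  }"), sfx, sfx, sfx, sfx, sfx)
      else sprintf("  for (c in 1:C) { d_%s[c,1] <- 0 }", sfx),
      "  for (c in 1:C) { for (t in 1:T) {",
      if (K > 0) sprintf("    xb_%s[c,t] <- inprod(X[c,t,1:K], gamma_%s[1:K])", sfx, sfx)
      else sprintf("    xb_%s[c,t] <- 0", sfx),
      "  } }"), collapse = "\n")
  }
  obs_blocks <- character(0)
  if (od$n > 0) {
    obs_blocks <- c(obs_blocks, paste(
      "  for (i in 1:N_obs) {",
      "    lat[i] <- Q[oind[i], oc[i], ot[i]] - oinfl[i] * log_infl[oreg[i]] + osign[i] * rb[oreg[i]]",
      "  }", sep = "\n"))
    if (any(types == "pp")) obs_blocks <- c(obs_blocks,
      "  for (i in 1:N_pp) { y_pp[i] ~ dnorm(lat[pp_idx[i]], prec_pp[i]) }")
    if (any(types == "tp")) obs_blocks <- c(obs_blocks, paste(
      "  for (i in 1:N_tp) {",
      "    ll_tp[i] <- logdensity.norm(y_tp[i], lat[tp_idx[i]], prec_tp[i]) - log(max(phi((u_tp[i] - lat[tp_idx[i]]) * sqrt(prec_tp[i])), 1.0E-300))",
      "    zeros_tp[i] ~ dpois(Cz - ll_tp[i])",
      "  }", sep = "\n"))
    if (any(types == "mn")) obs_blocks <- c(obs_blocks, paste(
      "  for (i in 1:N_mn) {",
      "    zeros_mn[i] ~ dpois(Cz - log(max(phi((lat[mn_idx[i]] - y_mn[i]) / s_mn[i]), 1.0E-300)))",
      "  }", sep = "\n"))
    if (any(types == "mx")) obs_blocks <- c(obs_blocks, paste(
      "  for (i in 1:N_mx) {",
      "    zeros_mx[i] ~ dpois(Cz - log(max(phi((y_mx[i] - lat[mx_idx[i]]) / s_mx[i]), 1.0E-300)))",
      "  }", sep = "\n"))
    if (any(types == "iv")) obs_blocks <- c(obs_blocks, paste(
      "  for (i in 1:N_iv) {",
      "    p_iv[i] <- phi((hi_iv[i] - lat[iv_idx[i]]) / s_iv[i]) - phi((y_iv[i] - lat[iv_idx[i]]) / s_iv[i])",
      "    zeros_iv[i] ~ dpois(Cz - log(max(p_iv[i], 1.0E-300)))",
      "  }", sep = "\n"))
  }
  paste(c(
    "model {",
    surface("om"), surface("al"),
    "  for (r in 1:R) { log_infl[r] ~ dlnorm(infl_meanlog, prec_linfl) }",
    "  mu_rb ~ dnorm(recall_mu0, prec_rb_mu)",
    "  sd_rb ~ dnorm(0, prec_rb_sd) T(0,)",
    "  for (r in 1:R) { rb[r] ~ dnorm(mu_rb, 1/(sd_rb*sd_rb)) }",
    "  for (f in 1:F) { for (c in 1:C) { for (t in 1:T) {",
    "    Omf[f,c,t] <- w[f,c,t] * exp(a_om[f] + b_om[c] + xb_om[c,t] + d_om[c,t]) * pw",
    "    th[f,c,t] <- ilogit(a_al[f] + b_al[c] + xb_al[c,t] + d_al[c,t])",
    "    Psif[f,c,t] <- Omf[f,c,t] * th[f,c,t] / 1.1",
    "    bif[f,c,t] <- Omf[f,c,t] * (1 - th[f,c,t]) / 1.2",
    "  } } }",
    "  for (c in 1:C) { for (t in 1:T) {",
    "    Omega[c,t] <- sum(Omf[1:F,c,t])",
    "    Psi[c,t] <- sum(Psif[1:F,c,t])",
    "    btot[c,t] <- sum(bif[1:F,c,t])",
    "    bu[c,t] <- inprod(bif[1:F,c,t], unintv[1:F])",
    "    pu[c,t] <- inprod(Omf[1:F,c,t], unintv[1:F])",
    "    bm[c,t] <- inprod(bif[1:F,c,t], marv[1:F])",
    "    bmi[c,t] <- inprod(bif[1:F,c,t], marintv[1:F])",
    "    Q[1,c,t] <- log(Psi[c,t])",
    "    Q[2,c,t] <- log(Psi[c,t]) - lograte_off[c,t]",
    "    Q[3,c,t] <- logit(bu[c,t] / btot[c,t])",
    "    Q[4,c,t] <- logit(pu[c,t] / Omega[c,t])",
    "    Q[5,c,t] <- logit(bmi[c,t] / bm[c,t])",
    "    B[c,t] ~ dnorm(btot[c,t], precB[c,t])",
    "  } }",
    obs_blocks,
    "}"), collapse = "\n")
}

jags_oracle_data <- function(model) {
  d <- model$data
  od <- model$obsdat
  pr <- d$priors
  data <- list(
    F = d$F, C = d$C, T = d$T, G = d$G, R = d$R,
    w = d$w, pw = d$pw, B = d$B, precB = 1 / d$sdB^2,
    lograte_off = d$lograte_off,
    unintv = as.numeric(d$unint), marv = as.numeric(d$married),
    marintv = as.numeric(d$married_intended), group = d$group,
    pm_a_om = pr$group_effects_omega, pm_a_al = pr$group_effects_alpha,
    prec_a = 1 / pr$sd_group_effect^2,
    mu_world_om = pr$mu_world_omega,
    prec_world_om = 1 / pr$sd_world_omega^2,
    mu_world_al = pr$mu_world_alpha,
    prec_world_al = 1 / pr$sd_world_alpha^2,
    prec_tau_scale = 1 / pr$sd_country_scale^2,
    prec_rw_scale = 1 / pr$rw_sd_scale^2,
    infl_meanlog = pr$infl_meanlog, prec_linfl = 1 / pr$infl_sdlog^2,
    recall_mu0 = pr$recall_mu0, prec_rb_mu = 1 / pr$recall_mu_sd^2,
    prec_rb_sd = 1 / pr$recall_sd_scale^2,
    Cz = 100)
  if (d$K > 0) {
    data$X <- d$X
    data$K <- d$K
    data$prec_coef <- 1 / pr$coef_sd^2
  }
  if (od$n > 0) {
    data$N_obs <- od$n
    data$oc <- od$ci; data$ot <- od$ti; data$oind <- od$oi
    data$oreg <- od$ri
    data$oinfl <- as.numeric(od$infl); data$osign <- od$osign
    for (tt in c("pp", "tp", "mn", "mx", "iv")) {
      idx <- which(od$type == tt)
      if (!length(idx)) next
      data[[paste0(tt, "_idx")]] <- idx
      data[[paste0("N_", tt)]] <- length(idx)
      data[[paste0("y_", tt)]] <- od$y[idx]
      if (tt %in% c("pp", "tp")) {
        data[[paste0("prec_", tt)]] <- 1 / od$vtot[idx]
      }
      if (tt == "tp") data$u_tp <- od$utr[idx]
      if (tt == "iv") data$hi_iv <- od$yhi[idx]
      if (tt %in% c("mn", "mx", "iv")) {
        data[[paste0("s_", tt)]] <- od$seff[idx]
      }
      if (tt %in% c("tp", "mn", "mx", "iv")) {
        data[[paste0("zeros_", tt)]] <- rep(0L, length(idx))
      }
    }
  }
  data
}

jags_oracle_fit <- function(model, n_adapt = 1000, n_burn = 1000,
                            n_iter = 4000, seed = 1) {
  skip_if_not_installed("rjags")
  code <- jags_oracle_code(model)
  data <- jags_oracle_data(model)
  con <- textConnection(code)
  on.exit(close(con))
  jm <- suppressWarnings(
    rjags::jags.model(con, data = data,
                      inits = list(.RNG.name = "base::Mersenne-Twister",
                                   .RNG.seed = seed),
                      n.chains = 1, n.adapt = n_adapt, quiet = TRUE))
  update(jm, n_burn, progress.bar = "none")
  monitors <- c("a_om", "a_al", "m_om", "m_al", "b_om", "b_al",
                "tau_om", "tau_al", "sig_rw_om", "sig_rw_al",
                "log_infl", "rb", "mu_rb", "sd_rb")
  if (model$data$K > 0) monitors <- c(monitors, "gamma_om", "gamma_al")
  samp <- rjags::coda.samples(jm, monitors, n.iter = n_iter,
                              progress.bar = "none")
  as.matrix(samp)
}
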