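test_that("world generation is deterministic and seed-split by country", {
  w1 <- generate_world(world_config(n_regions = 2, countries_per_region = 3,
                                    seed = 5))
  w2 <- generate_world(world_config(n_regions = 2, countries_per_region = 3,
                                    seed = 5))
  expect_identical(w1$params, w2$params)
  expect_identical(w1$exposure$women, w2$exposure$women)
  w3 <- generate_world(world_config(n_regions = 2, countries_per_region = 3,
                                    seed = 6))
  expect_false(identical(w1$params$b_om, w3$params$b_om))
  # adding countries leaves existing countries' draws untouched
  w4 <- generate_world(world_config(n_regions = 2, countries_per_region = 4,
                                    seed = 5))
  expect_equal(w4$params$b_om[1:6], w1$params$b_om)
  expect_equal(w4$exposure$women[, 1:6, ], w1$exposure$women,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(world_config(n_regions = 2), "seed")
})

test_that("near-zero innovation scale gives flat period trajectories", {
  pr <- default_priors()
  pr$rw_sd_scale <- 1e-9
  zero_g <- c(gdp_pc = 0, legal_status = 0)
  w <- generate_world(world_config(n_regions = 1, countries_per_region = 2,
                                   priors = pr, gamma_omega = zero_g,
                                   gamma_alpha = zero_g, seed = 3))
  expect_lt(max(abs(w$params$d_om)), 1e-7)
  expect_lt(max(abs(apply(log(w$rates$omega[1, , ]), 1, sd))), 1e-6)
})

test_that("simulated group means obey the law of large numbers", {
  w <- generate_world(world_config(n_regions = 2,
                                   countries_per_region = 250, seed = 9))
  gidx <- match(w$countries$modeling_group,
                sort(unique(w$countries$modeling_group)))
  for (g in 1:2) {
    emp <- mean(w$params$b_al[gidx == g])
    expect_lt(abs(emp - w$params$m_al[g]),
              4 * w$params$tau_al / sqrt(sum(gidx == g)) + 0.02)
  }
})

test_that("accounts in the truth bundle come from the accounting module", {
  w <- generate_world(world_config(n_regions = 2, countries_per_region = 2,
                                   seed = 13))
  acc <- pregnancy_accounts(w$exposure, w$rates)
  expect_equal(acc$Psi, w$accounts$Psi)
  expect_equal(acc$Omega, acc$births + acc$Psi + acc$misc)
  # UNPD births hug implied births within a few percent
  rel <- abs(w$exposure$births - acc$births) / acc$births
  expect_lt(max(rel), 0.1)
})

test_that("registries report truth up to noise and flagged datums classify as minimums", {
  sim <- tiny_world(seed = 31)
  truth <- sim$truth; raw <- sim$raw
  regimes <- raw$regimes
  ab <- raw$abortion
  ab$psi <- mapply(function(cc, pp) {
    truth$accounts$Psi[match(cc, truth$exposure$countries),
                       match(pp, truth$exposure$periods)]
  }, ab$country, ab$period)
  complete <- ab[regimes[ab$country] == "complete_registry" &
                   !ab$includes_spontaneous, ]
  expect_true(all(abs(log(complete$reported_count / complete$psi)) < 0.5))
  incomplete <- ab[regimes[ab$country] == "incomplete_registry", ]
  cls <- classify_abortion_data(incomplete, raw$regions_with_underreporting)
  expect_true(all(cls$bound == "minimum"))
  # generated minimums fall below the truth on average
  expect_lt(mean(incomplete$reported_count / incomplete$psi), 1)
})

test_that("observation generation is deterministic given the seed", {
  truth <- generate_world(world_config(n_regions = 2,
                                       countries_per_region = 3, seed = 7))
  r1 <- generate_observations(truth, obs_config(seed = 8))
  r2 <- generate_observations(truth, obs_config(seed = 8))
  expect_identical(r1$abortion, r2$abortion)
  expect_identical(r1$intention, r2$intention)
  expect_error(obs_config(), "seed")
  expect_error(obs_config(seed = 1, regimes = c(complete_registry = 0.5)),
               "sum to 1")
})

test_that("the default configuration exercises every classification branch", {
  sim <- tiny_world(seed = 41, n_regions = 4, countries_per_region = 5)
  obs <- sim$obs; raw <- sim$raw
  audit <- paste(obs$audit, collapse = " | ")
  # abortion tree
  expect_true(any(obs$excluded &
                    obs$datum_id %in% raw$abortion$datum_id))
  expect_match(audit, "no national probability sample")
  expect_match(audit, "no regional under-reporting estimate")
  expect_match(audit, "regional under-reporting estimate available")
  expect_match(audit, "subgroup breakdown")
  expect_match(audit, "AICM point estimate")
  expect_match(audit, "modified AICM")
  expect_match(audit, "legal abortion not broadly available")
  expect_match(audit, "acknowledged completeness")
  expect_match(audit, "below a women's-survey estimate")
  expect_match(audit, "informal-sector provision")
  expect_match(audit, "implausible level or trend")
  expect_match(audit, "all official-statistic questions pass")
  expect_match(audit, "includes spontaneous abortions: interval")
  expect_match(audit, "minimum revised downward")
  # intention tree
  expect_true(any(obs$excluded &
                    obs$datum_id %in% raw$intention$datum_id))
  expect_match(audit, "mean sampling error")
  expect_match(audit, "survey's own sampling error")
  expect_match(audit, "recall over one year")
  expect_match(audit, "LMUP instrument")
  expect_match(audit, "antenatal-clinic sample")
  expect_match(audit, "all women sampled")
  expect_match(audit, "ever-married women sampled")
  expect_match(audit, "recent births identifiable")
  expect_match(audit, "maximum percent intended among all women")
  expect_match(audit, "no marital history: range")
})

test_that("the recovery report is exact for a degenerate posterior and permutation-invariant", {
  w <- generate_world(world_config(n_regions = 2, countries_per_region = 2,
                                   seed = 17))
  p <- w$params
  cols <- c(sprintf("a_om[%d]", 1:6), sprintf("a_al[%d]", 1:6),
            sprintf("m_om[%d]", 1:2), sprintf("m_al[%d]", 1:2),
            sprintf("b_om[%d]", 1:4), sprintf("b_al[%d]", 1:4),
            sprintf("gamma_om[%d]", 1:2), sprintf("gamma_al[%d]", 1:2),
            sprintf("log_infl[%d]", 1:2), sprintf("rb[%d]", 1:2))
  vals <- c(p$a_om, p$a_al, p$m_om, p$m_al, p$b_om, p$b_al,
            unname(p$gamma_om), unname(p$gamma_al), p$log_infl, p$rb)
  draws <- matrix(rep(vals, each = 10), nrow = 10,
                  dimnames = list(NULL, cols))
  rep1 <- recovery_report(w, draws)
  expect_true(all(rep1$rmse == 0))
  expect_true(all(rep1$coverage95 == 1))
  # coverage matches a hand count on perturbed draws
  draws2 <- draws
  draws2[, "m_om[1]"] <- draws2[, "m_om[1]"] + 10  # truth now outside
  rep2 <- recovery_report(w, draws2, families = "m_om")
  expect_equal(rep2$coverage95, 0.5)
  # rmse invariant to country ordering
  perm <- c(3, 1, 4, 2)
  draws3 <- draws
  draws3[, sprintf("b_om[%d]", 1:4)] <- draws[, sprintf("b_om[%d]", perm)]
  w_perm <- w
  w_perm$params$b_om <- w$params$b_om[perm]
  expect_equal(recovery_report(w_perm, draws3, families = "b_om")$rmse,
               recovery_report(w, draws, families = "b_om")$rmse)
  expect_error(recovery_report(w, draws[, 1:3, drop = FALSE]),
               "index mismatch")
})
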