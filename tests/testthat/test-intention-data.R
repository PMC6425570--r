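test_that("the LMUP bracketing returns [unwanted, unwanted + ambivalent]", {
  expect_equal(lmup_interval(50, 20, 30), c(low = 30, high = 50))
  expect_equal(lmup_interval(100, 0, 0), c(low = 0, high = 0))
  expect_equal(lmup_interval(0, 100, 0), c(low = 0, high = 100))
  expect_error(lmup_interval(50, 20, 40), "sum")
  set.seed(3)
  for (i in 1:50) {
    u <- runif(1, 0, 60); a <- runif(1, 0, 100 - u); p <- 100 - u - a
    iv <- lmup_interval(p, a, u)
    expect_equal(unname(iv["high"] - iv["low"]), a)
    expect_equal(unname(iv["high"]), 100 - p)
    # complement datum gives the mirrored interval
    ivc <- lmup_interval(u, a, p)
    expect_equal(unname(ivc), unname(100 - rev(iv)))
  }
})

test_that("survey scope resolves targets and bounds as specified", {
  s <- marital_scope(intent_datum(scope = "all_women"))
  expect_true(s$all_women_target && s$marital_target)
  s <- marital_scope(intent_datum(scope = "ever_married"))
  expect_true(!s$all_women_target && s$marital_target)
  s <- marital_scope(intent_datum(scope = "currently_married",
                                  recent_birth_restriction = TRUE))
  expect_true(!s$all_women_target && s$marital_target)
  s <- marital_scope(intent_datum(scope = "currently_married",
                                  recent_birth_restriction = FALSE))
  expect_true(s$all_women_target && !s$marital_target)
  expect_equal(s$all_women_bound, "minimum")
  expect_error(marital_scope(intent_datum(scope = "men")), "scope")
})

test_that("classification emits the expected observations per scope", {
  # all women with microdata: point on percent of births unintended with
  # the survey's own SE, plus a marital-births observation
  out <- classify_intention_datum(
    intent_datum(percent_marital_unintended = 35), mean_sampling_error = 3)
  expect_equal(nrow(out), 2L)
  aw <- out[out$indicator == "percent_births_unintended", ]
  expect_equal(aw$bound, "point")
  expect_equal(aw$value, 40)
  expect_equal(aw$sampling_se, 2)
  mar <- out[out$indicator == "percent_marital_births_intended", ]
  expect_equal(mar$value, 65)
  expect_true("subgroup" %in% names(parse_components(mar$error_components)))
  # ever married: marital point only
  out2 <- classify_intention_datum(intent_datum(scope = "ever_married"), 3)
  expect_equal(out2$indicator, "percent_marital_births_intended")
  expect_equal(out2$value, 60)
  # currently married without the recent-birth restriction: minimum on the
  # all-women percent unintended (maximum percent intended)
  out3 <- classify_intention_datum(
    intent_datum(scope = "currently_married",
                 recent_birth_restriction = FALSE), 3)
  expect_equal(out3$bound, "minimum")
  expect_equal(out3$indicator, "percent_births_unintended")
  # special population excluded
  expect_true(classify_intention_datum(
    intent_datum(special_population = TRUE), 3)$excluded)
})

test_that("sampling-error fallbacks and recall flags follow the rules", {
  own <- classify_intention_datum(intent_datum(microdata_available = FALSE,
                                               sampling_error = 1.5), 3)
  expect_equal(own$sampling_se[1], 1.5)
  fallback <- classify_intention_datum(
    intent_datum(microdata_available = FALSE, sampling_error = NA_real_), 3)
  expect_equal(fallback$sampling_se[1], 3)
  expect_match(fallback$audit[1], "mean sampling error")
  rec <- classify_intention_datum(
    intent_datum(microdata_available = FALSE, sampling_error = 2,
                 recall_over_one_year = TRUE), 3)
  expect_true(all(rec$recall_flag))
  norec <- classify_intention_datum(
    intent_datum(recall_over_one_year = TRUE), 3)  # microdata available
  expect_false(any(norec$recall_flag))
  tab <- rbind(intent_datum(datum_id = "a", sampling_error = 2),
               intent_datum(datum_id = "b", sampling_error = 4),
               intent_datum(datum_id = "c", sampling_error = NA_real_,
                            microdata_available = FALSE))
  expect_equal(mean_sampling_error(tab), 3)
  out <- classify_intention_data(tab)
  expect_equal(out$sampling_se[out$datum_id == "c"][1], 3)
})

test_that("antenatal-clinic samples are recorded against the births denominator", {
  d <- intent_datum(microdata_available = FALSE, denominator = "pregnancies",
                    antenatal_clinic_sample = TRUE)
  out <- classify_intention_datum(d, 3)
  expect_true("percent_births_unintended" %in% out$indicator)
  d2 <- intent_datum(microdata_available = FALSE,
                     denominator = "pregnancies")
  out2 <- classify_intention_datum(d2, 3)
  expect_true("percent_pregnancies_unintended" %in% out2$indicator)
})

test_that("marital-history bounds bracket every assignment of ambiguous births", {
  rec <- function(n, marital, ambiguous, intended) {
    data.frame(birth_date = rep(2010, n),
               first_union_date = rep(if (marital || ambiguous) 2005 else
                 NA_real_, n),
               currently_in_first_union = rep(!ambiguous, n),
               intended = rep_len(intended, n))
  }
  # 10 definite marital intended + 2 ambiguous unintended
  records <- rbind(rec(10, TRUE, FALSE, TRUE), rec(2, FALSE, TRUE, FALSE))
  iv <- marital_history_bounds(records)
  expect_equal(unname(iv), c(100 * 10 / 12, 100), tolerance = 1e-10)
  # no ambiguous records: degenerate interval
  iv0 <- marital_history_bounds(rbind(rec(5, TRUE, FALSE, TRUE),
                                      rec(5, TRUE, FALSE, FALSE)))
  expect_equal(unname(iv0), c(50, 50))
  # all ambiguous: widest attainable interval
  iva <- marital_history_bounds(rbind(rec(3, FALSE, TRUE, TRUE),
                                      rec(3, FALSE, TRUE, FALSE)))
  expect_equal(unname(iva), c(0, 100))
  # exhaustive enumeration oracle for mixed assignments
  set.seed(8)
  for (rep in 1:10) {
    n_mar <- sample(0:4, 1); n_amb <- sample(1:6, 1)
    records <- rbind(
      if (n_mar > 0) rec(n_mar, TRUE, FALSE, runif(n_mar) < 0.5),
      rec(n_amb, FALSE, TRUE, runif(n_amb) < 0.5))
    iv <- marital_history_bounds(records)
    amb_rows <- which(!records$currently_in_first_union)
    I0 <- sum(records$intended[-amb_rows][
      !is.na(records$first_union_date[-amb_rows])])
    if (n_mar == 0) I0 <- 0
    for (mask in 0:(2^n_amb - 1)) {
      inc <- amb_rows[bitwAnd(mask, 2^(seq_len(n_amb) - 1)) > 0]
      n_m <- n_mar + length(inc)
      if (n_m == 0) next
      pct <- 100 * (I0 + sum(records$intended[inc])) / n_m
      expect_gte(pct, iv[["low"]] - 1e-9)
      expect_lte(pct, iv[["high"]] + 1e-9)
    }
  }
  expect_error(marital_history_bounds(records[0, ]), "nonempty")
  bad <- data.frame(birth_date = 2010, first_union_date = 2005,
                    currently_in_first_union = NA, intended = TRUE)
  expect_error(marital_history_bounds(bad), "union")
})

test_that("microdata without a marital history yield an interval from birth records", {
  set.seed(4)
  records <- make_birth_records_fixture()
  d <- intent_datum(marital_history_available = FALSE,
                    percent_marital_unintended = 35)
  out <- classify_intention_datum(d, 3, birth_records = records)
  mar <- out[out$indicator == "percent_marital_births_intended", ]
  expect_equal(mar$bound, "interval")
  expect_lte(mar$value, mar$value_high)
  # without records: point fallback with an audit note
  out2 <- classify_intention_datum(d, 3)
  mar2 <- out2[out2$indicator == "percent_marital_births_intended", ]
  expect_equal(mar2$bound, "point")
  expect_match(mar2$audit, "no birth records")
})

test_that("the intention tree is total under flag fuzzing", {
  grid <- expand.grid(
    special = c(TRUE, FALSE), national = c(TRUE, FALSE),
    micro = c(TRUE, FALSE), se_known = c(TRUE, FALSE),
    recall = c(TRUE, FALSE),
    scope = c("all_women", "ever_married", "currently_married"),
    denom = c("births", "pregnancies"), antenatal = c(TRUE, FALSE),
    lmup = c(TRUE, FALSE), restrict = c(TRUE, FALSE),
    stringsAsFactors = FALSE)
  set.seed(5)
  grid <- grid[sample(nrow(grid), 400), ]
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    d <- intent_datum(special_population = g$special,
                      national_probability_sample = g$national,
                      microdata_available = g$micro,
                      sampling_error = if (g$se_known) 2 else NA_real_,
                      recall_over_one_year = g$recall, scope = g$scope,
                      denominator = g$denom,
                      antenatal_clinic_sample = g$antenatal,
                      recent_birth_restriction = g$restrict,
                      percent_marital_unintended = 30)
    if (g$lmup) {
      d$instrument <- "lmup"
      d$lmup_planned <- 55; d$lmup_ambivalent <- 15; d$lmup_unwanted <- 30
    }
    out <- classify_intention_datum(d, 3)
    expect_true(all(out$excluded |
                      out$bound %in% c("point", "minimum", "interval")))
    expect_true(all(out$excluded | nchar(out$error_components) > 0))
  }
})
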