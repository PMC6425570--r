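test_that("special population samples are excluded", {
  obs <- classify_abortion_datum(study_datum(special_population = TRUE))
  expect_true(obs$excluded)
  expect_match(obs$exclusion_reason, "special population")
})

test_that("women's-report surveys are minimums without a regional under-reporting estimate", {
  d <- study_datum(national_probability_sample = TRUE)
  obs <- classify_abortion_datum(d, region_has_underreporting_estimate = FALSE)
  expect_equal(obs$bound, "minimum")
  obs2 <- classify_abortion_datum(d, region_has_underreporting_estimate = TRUE)
  expect_equal(obs2$bound, "point")
  expect_equal(obs2$inflation_link, "regional_inflation_factor")
})

test_that("non-national samples and subgroup breakdowns add error components", {
  d <- study_datum(national_probability_sample = FALSE,
                   subgroup_breakdown = TRUE)
  obs <- classify_abortion_datum(d, region_has_underreporting_estimate = TRUE)
  comps <- parse_components(obs$error_components)
  expect_true(all(c("non_probability", "subgroup") %in% names(comps)))
  d2 <- study_datum()
  obs2 <- classify_abortion_datum(d2, TRUE)
  comps2 <- parse_components(obs2$error_components)
  expect_false("non_probability" %in% names(comps2))
  expect_equal(length(comps), length(parse_components(
    classify_abortion_datum(study_datum(national_probability_sample = FALSE),
                            TRUE)$error_components)) + 1L)
  expect_length(subgroup_error(list(subgroup_breakdown = TRUE)), 1L)
  expect_length(subgroup_error(list(subgroup_breakdown = FALSE)), 0L)
})

test_that("official statistics follow the six questions in printed order", {
  expect_equal(classify_official(official_datum(
    legal_broadly_available = FALSE))$bound, "minimum")
  expect_equal(classify_official(official_datum(
    acknowledged_completeness = 0.85))$bound, "minimum")
  expect_equal(classify_official(official_datum(
    below_survey_estimate = TRUE))$bound, "minimum")
  expect_equal(classify_official(official_datum(
    informal_sector_substantial = TRUE))$bound, "minimum")
  expect_equal(classify_official(official_datum(
    implausible_per_review = TRUE))$bound, "minimum")
  all_pass <- classify_official(official_datum())
  expect_equal(all_pass$bound, "point")
  expect_true("nonsampling_default" %in%
                names(parse_components(all_pass$error_components)))
  # unknown completeness proceeds (claimed complete)
  expect_equal(classify_official(official_datum(
    acknowledged_completeness = NA_real_))$bound, "point")
})

test_that("the completeness cutoff flips point to minimum exactly at 90%", {
  cl <- function(x) classify_official(official_datum(
    acknowledged_completeness = x))$bound
  expect_equal(cl(0.90), "point")
  expect_equal(cl(0.8999), "minimum")
  sweep <- vapply(seq(0.80, 0.99, by = 0.01), cl, "")
  expect_equal(100 * (seq(0.80, 0.99, by = 0.01)[sweep == "point"][1]), 90)
})

test_that("a datum failing question k is unaffected by later answers", {
  base <- official_datum(legal_broadly_available = FALSE)
  variants <- list(
    official_datum(legal_broadly_available = FALSE,
                   informal_sector_substantial = TRUE),
    official_datum(legal_broadly_available = FALSE,
                   implausible_per_review = TRUE),
    official_datum(legal_broadly_available = FALSE,
                   acknowledged_completeness = 0.5))
  ref <- classify_official(base)
  for (v in variants) {
    got <- classify_official(v)
    expect_equal(got$bound, ref$bound)
    expect_equal(got$value, ref$value)
  }
  # except question 6: the spontaneous adjustment also applies to minimums
  sp <- classify_official(official_datum(legal_broadly_available = FALSE,
                                         includes_spontaneous = TRUE,
                                         reported_count = 110,
                                         live_births = 0))
  expect_equal(sp$bound, "minimum")
  expect_equal(sp$value, 100)
})

test_that("the spontaneous adjustment solves the pregnancy identity", {
  expect_equal(spontaneous_adjust(110, 0), c(low = 100, high = 110))
  expect_equal(spontaneous_adjust(22, 100),
               c(low = (22 - 20) / 1.1, high = 22))
  expect_equal(spontaneous_adjust(10, 100), c(low = 0, high = 10))
  # round-trip: an interior lower bound plugged back into the identity
  # reproduces the reported count m = 1.1 a + 0.2 b
  set.seed(2)
  for (i in 1:50) {
    b <- runif(1, 0, 1000); m <- runif(1, 0.25 * b, 5000)
    a <- spontaneous_adjust(m, b)[["low"]]
    if (a > 0) expect_equal(1.1 * a + 0.2 * b, m, tolerance = 1e-10)
  }
  off <- classify_official(official_datum(includes_spontaneous = TRUE,
                                          reported_count = 110,
                                          live_births = 0))
  expect_equal(off$bound, "interval")
  expect_equal(off$value, 100)
  expect_equal(off$value_high, 110)
})

test_that("AICM observations carry multiplier and complications errors with right truncation", {
  d <- study_datum(method = "aicm", complications_treated = 1000,
                   multiplier = 5, total_complications = 1200,
                   national_probability_sample = TRUE)
  obs <- aicm_observation(d)
  expect_equal(obs$bound, "point")
  expect_equal(obs$value, 5000)
  comps <- parse_components(obs$error_components)
  expect_setequal(names(comps), c("multiplier", "complications"))
  expect_equal(obs$truncation, 6000)
  mod <- aicm_observation(within(d, legal_abortions <- 2000))
  expect_equal(mod$bound, "minimum")
  expect_setequal(names(parse_components(mod$error_components)),
                  c("multiplier", "complications", "legal_count"))
  expect_error(aicm_observation(study_datum(method = "aicm")), "multiplier")
  expect_error(classify_abortion_datum(study_datum(
    method = "aicm", complications_treated = 100,
    total_complications = 50, multiplier = 5)), "exceeds")
})

test_that("the decision tree is total over the boolean field grid", {
  grid <- expand.grid(
    source = c("published_study", "official_statistic"),
    special_population = c(TRUE, FALSE),
    national_probability_sample = c(TRUE, FALSE),
    method_study = c("womens_reports", "aicm"),
    subgroup_breakdown = c(TRUE, FALSE),
    legal_broadly_available = c(TRUE, FALSE),
    completeness = c(NA, 0.5, 0.95),
    below_survey_estimate = c(NA, TRUE, FALSE),
    informal_sector_substantial = c(TRUE, FALSE),
    implausible_per_review = c(TRUE, FALSE),
    includes_spontaneous = c(TRUE, FALSE),
    region_est = c(TRUE, FALSE),
    stringsAsFactors = FALSE)
  set.seed(1)
  grid <- grid[sample(nrow(grid), 600), ]
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    d <- official_datum(source = g$source,
                        special_population = g$special_population,
                        national_probability_sample =
                          g$national_probability_sample,
                        subgroup_breakdown = g$subgroup_breakdown,
                        legal_broadly_available = g$legal_broadly_available,
                        acknowledged_completeness = g$completeness,
                        below_survey_estimate = g$below_survey_estimate,
                        informal_sector_substantial =
                          g$informal_sector_substantial,
                        implausible_per_review = g$implausible_per_review,
                        includes_spontaneous = g$includes_spontaneous)
    if (g$source == "published_study") {
      d$method <- g$method_study
      if (g$method_study == "aicm") {
        d$complications_treated <- 800; d$multiplier <- 4
        d$total_complications <- 900
      }
    }
    obs <- classify_abortion_datum(d, g$region_est)
    expect_true(obs$excluded ||
                  obs$bound %in% c("point", "minimum", "maximum", "interval"))
  }
  expect_error(classify_abortion_datum(official_datum(source = "blog")),
               "unclassifiable")
  expect_error(classify_abortion_datum(study_datum(method = "registry")),
               "unclassifiable")
})

test_that("classification is deterministic and below-survey flags propagate within a country", {
  d <- study_datum(subgroup_breakdown = TRUE)
  expect_identical(classify_abortion_datum(d, TRUE),
                   classify_abortion_datum(d, TRUE))
  tab <- rbind(
    official_datum(datum_id = "a", period = 1990L,
                   below_survey_estimate = TRUE),
    official_datum(datum_id = "b", period = 1995L),
    official_datum(datum_id = "c", period = 2000L,
                   period_quality_established = TRUE),
    within(official_datum(datum_id = "d", period = 1990L), {
      country <- "C02"
    }))
  out <- classify_abortion_data(tab)
  expect_equal(out$bound[out$datum_id == "a"], "minimum")
  expect_equal(out$bound[out$datum_id == "b"], "minimum")  # propagated
  expect_equal(out$bound[out$datum_id == "c"], "point")    # exception
  expect_equal(out$bound[out$datum_id == "d"], "point")    # other country
})

test_that("abortion datum tables round-trip through delimited text", {
  tab <- rbind(official_datum(datum_id = "a"),
               study_datum(datum_id = "b", subgroup_breakdown = TRUE))
  f <- tempfile(fileext = ".tsv")
  utils::write.table(tab, f, sep = "\t", row.names = FALSE, quote = FALSE,
                     na = "")
  back <- read_abortion_data(f)
  expect_equal(back$datum_id, c("a", "b"))
  expect_true(is.logical(back$subgroup_breakdown))
  expect_true(is.na(back$acknowledged_completeness[1]))
  unlink(f)
})
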