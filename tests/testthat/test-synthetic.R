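test_that("generator hits the configured COPD prevalence and is reproducible", {
  cfg <- generator_config(n = 100000, seed = 101)
  cohort <- generate_cohort(cfg)
  frac <- mean(identify_copd(cohort))
  se <- sqrt(0.122 * (1 - 0.122) / 100000)
  expect_lt(abs(frac - 0.122), 3 * se)

  # byte-identical under the same seed
  again <- generate_cohort(cfg)
  expect_identical(cohort, again)
  different <- generate_cohort(generator_config(n = 100, seed = 101))
  shifted <- generate_cohort(generator_config(n = 100, seed = 102))
  expect_false(identical(different, shifted))
})

test_that("empirical death rate matches the generator's own probabilities", {
  cfg <- generator_config(n = 100000, seed = 55)
  cohort <- generate_cohort(cfg)
  p <- implied_outcome_probability(cohort, cfg)
  se <- sqrt(mean(p * (1 - p))) / sqrt(length(p))
  expect_lt(abs(mean(cohort$died_6m) - mean(p)), 3 * se)
})

test_that("implied outcome probability follows the logistic model exactly", {
  rec <- make_record("p", oad_indicator = TRUE, smoking = "current")

  # all coefficients zero: inverse-logit of 0
  flat <- generator_config(
    outcome_coefficients = c(intercept = 0, age = 0, heart_rate = 0,
                             systolic_bp = 0, creatinine = 0,
                             diuretic_in_hospital = 0, cardiac_arrest = 0,
                             st_deviation = 0, elevated_markers = 0),
    copd_log_odds_offset = 0, diabetes_log_odds_offset = 0)
  expect_equal(implied_outcome_probability(rec, flat), 0.5)

  # the COPD offset multiplies the odds by exactly exp(delta)
  with_offset <- generator_config(
    outcome_coefficients = flat$outcome_coefficients,
    copd_log_odds_offset = 0.5, diabetes_log_odds_offset = 0)
  p0 <- implied_outcome_probability(rec, flat)
  p1 <- implied_outcome_probability(rec, with_offset)
  expect_equal((p1 / (1 - p1)) / (p0 / (1 - p0)), exp(0.5), tolerance = 1e-12)

  # hand-computed inverse-logit for a printed coefficient vector
  cfg <- generator_config(
    outcome_coefficients = c(intercept = -2, age = 0.8, heart_rate = 0.3,
                             systolic_bp = -0.4, creatinine = 0.25,
                             diuretic_in_hospital = 0.7, cardiac_arrest = 1.1,
                             st_deviation = 0.5, elevated_markers = 0.2),
    copd_log_odds_offset = 0.6, diabetes_log_odds_offset = 0.1)
  rec2 <- make_record("q", age = 72, heart_rate = 95, systolic_bp = 118,
                      creatinine = 140, diuretic_in_hospital = TRUE,
                      cardiac_arrest = FALSE, st_deviation = TRUE,
                      elevated_markers = FALSE, oad_indicator = TRUE,
                      smoking = "ex", diabetes = TRUE)
  lp <- -2 + 0.8 * (72 - 70) / 15 + 0.3 * (95 - 80) / 22 +
    (-0.4) * (118 - 140) / 29 + 0.25 * (log(140) - log(100)) / 0.5 +
    0.7 * 1 + 1.1 * 0 + 0.5 * 1 + 0.2 * 0 + 0.6 * 1 + 0.1 * 1
  expect_equal(implied_outcome_probability(rec2, cfg), 1 / (1 + exp(-lp)),
               tolerance = 1e-12)
})

test_that("group-conditional covariate means match the configuration", {
  cfg <- generator_config(n = 60000, seed = 77)
  cohort <- generate_cohort(cfg)
  copd <- identify_copd(cohort)
  # Monte-Carlo error on a mean of ~7000 draws with sd ~24 is ~0.3 bpm
  expect_equal(mean(cohort$heart_rate[!copd]), 80.2, tolerance = 0.02)
  expect_equal(mean(cohort$heart_rate[copd]), 87.2, tolerance = 0.02)
  expect_equal(mean(cohort$systolic_bp[!copd]), 139.9, tolerance = 0.02)
  expect_equal(mean(cohort$creatinine[copd]), 103.4, tolerance = 0.05)
  expect_lt(abs(mean(cohort$diuretic_in_hospital[copd]) - 0.325),
            3 * sqrt(0.325 * 0.675 / sum(copd)))
  expect_true(all(cohort$smoking[copd] %in% c("ex", "current")))
  expect_true(all(cohort$oad_indicator[copd]))
})

test_that("default mortality lies between the two group anchor rates", {
  cohort <- small_synthetic_cohort(n = 50000, seed = 88)
  copd <- identify_copd(cohort)
  overall <- mean(cohort$died_6m)
  expect_gt(overall, 0.10)
  expect_lt(overall, 0.14)
  # the subgroup's crude mortality exceeds the rest, same ordering as the
  # registry anchors (17.7% vs 11.6%)
  expect_gt(mean(cohort$died_6m[copd]), mean(cohort$died_6m[!copd]))
})

test_that("missingness injection is exact at the edges and binomial in between", {
  cohort <- small_synthetic_cohort(n = 10000, seed = 31)
  expect_identical(inject_missingness(cohort, c(creatinine = 0)), cohort)
  all_gone <- inject_missingness(cohort, c(smoking = 1))
  expect_true(all(is.na(all_gone$smoking)))
  some <- inject_missingness(cohort, c(creatinine = 0.2), seed = 9)
  frac <- mean(is.na(some$creatinine))
  expect_lt(abs(frac - 0.2), 3 * sqrt(0.2 * 0.8 / 10000))
  expect_error(inject_missingness(cohort, c(creatinine = 1.5)), "\\[0, 1\\]")
})

test_that("invalid configurations are rejected", {
  expect_error(generator_config(copd_prevalence = 1.2), "config error")
  expect_error(generator_config(n = 0), "n must be")
  expect_error(generator_config(nonsense = 1), "unknown generator config")
  bad_smoking <- generator_config()
  bad_smoking$smoking_probs$copd <- c(never = 0.2, ex = 0.5, current = 0.3)
  expect_error(generate_cohort(bad_smoking), "zero mass on 'never'")
})

test_that("generator configurations round-trip through JSON and YAML", {
  cfg <- generator_config(n = 123, seed = 9, copd_prevalence = 0.15,
                          copd_log_odds_offset = 0.4)
  for (ext in c(".json", ".yaml")) {
    path <- withr::local_tempfile(fileext = ext)
    write_generator_config(cfg, path)
    back <- read_generator_config(path)
    expect_identical(generate_cohort(back), generate_cohort(cfg), label = ext)
  }
  expect_error(read_generator_config("nope.json"), "not found")
})
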