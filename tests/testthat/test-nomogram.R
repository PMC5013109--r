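test_that("per-variable points follow the step-function and boolean rules", {
  ng <- test_nomogram()
  expect_equal(points_for_variable("age", 65, ng), 10)
  expect_equal(points_for_variable("age", 40, ng), 0)    # boundary joins its interval
  expect_equal(points_for_variable("age", 80, ng), 20)
  expect_equal(points_for_variable("age", 95, ng), 20)   # above last breakpoint
  expect_equal(points_for_variable("age", 39, ng), 0)    # clamped below range
  expect_equal(points_for_variable("cardiac_arrest", FALSE, ng), 0)
  expect_equal(points_for_variable("cardiac_arrest", TRUE, ng), 25)
  expect_error(points_for_variable("shoe_size", 42, ng), "unknown")
  expect_error(points_for_variable("age", NA, ng), "missing")

  # random values agree with an independent linear-search oracle
  set.seed(42)
  vals <- runif(200, 20, 110)
  v <- ng$variables$age
  expect_equal(points_for_variable("age", vals, ng),
               oracle_step_points(vals, v$breakpoints, v$points))
})

test_that("the total score is the sum of per-variable points", {
  ng <- test_nomogram()
  # a record sitting in the zero-point interval of every variable
  zero <- make_record("z", age = 30, heart_rate = 60, systolic_bp = 170,
                      creatinine = 40, st_deviation = FALSE,
                      elevated_markers = FALSE)
  expect_equal(grace_score(zero, ng), 0)

  # toggling the diuretic flag adds exactly the heart-failure points
  with_hf <- zero
  with_hf$diuretic_in_hospital <- TRUE
  expect_equal(grace_score(with_hf, ng) - grace_score(zero, ng), 20)

  # random records: compositional oracle over the eight variables
  cohort <- small_synthetic_cohort(n = 50, seed = 13)
  total <- Reduce(`+`, lapply(names(ng$variables), function(nm) {
    points_for_variable(nm, cohort[[nm]], ng)
  }))
  expect_equal(grace_score(cohort, ng), total)

  # any missing score input makes the record unscoreable
  incomplete <- make_record("m", creatinine = NA)
  expect_true(is.na(grace_score(incomplete, ng)))
})

test_that("score-to-risk interpolates between anchors and clamps outside", {
  ng <- test_nomogram()
  expect_equal(score_to_risk(40, ng), 0.02)         # exact anchor
  expect_equal(score_to_risk(60, ng), (0.02 + 0.08) / 2)  # midpoint
  expect_equal(score_to_risk(1000, ng), 0.60)       # clamp above
  expect_equal(score_to_risk(-10, ng), 0.005)       # clamp below
  ng2 <- nomogram(list(s = list(type = "binary", points = 1)),
                  data.frame(score = c(100, 120), risk = c(0.10, 0.20)))
  expect_equal(score_to_risk(110, ng2), 0.15)

  # non-decreasing over a fine grid spanning beyond the anchors
  grid <- seq(-20, 200, by = 0.5)
  expect_true(all(diff(score_to_risk(grid, ng)) >= 0))
})

test_that("risk bands follow the documented boundary conventions", {
  expect_equal(as.character(stratify_risk(c(0.029, 0.03, 0.06, 0.061))),
               c("low", "moderate", "moderate", "high"))
  expect_error(stratify_risk(1.2), "\\[0, 1\\]")
  expect_error(risk_bands(0.06, 0.03), "low_upper < moderate_upper")

  # order preservation: higher risk never maps to a lower band
  set.seed(7)
  r <- sort(runif(100))
  b <- stratify_risk(r)
  expect_true(all(diff(as.integer(b)) >= 0))
})

test_that("cohort prediction counts drops and matches record-wise composition", {
  ng <- test_nomogram()
  cohort <- make_cohort(make_record("a"), make_record("b", age = 85),
                        make_record("c", cardiac_arrest = TRUE))
  res <- predict_cohort(cohort, ng)
  expect_equal(nrow(res$predictions), 3)
  expect_equal(res$n_dropped, 0)

  cohort$creatinine[2] <- NA
  res <- predict_cohort(cohort, ng)
  expect_equal(nrow(res$predictions), 2)
  expect_equal(res$n_dropped, 1)

  # record-wise equality with grace_score . score_to_risk
  scored <- small_synthetic_cohort(n = 100, seed = 19)
  res <- predict_cohort(scored, ng)
  expect_equal(res$predictions$risk,
               score_to_risk(grace_score(scored, ng), ng))
  expect_equal(res$predictions$band, stratify_risk(res$predictions$risk))

  allna <- make_cohort(make_record("x", age = NA), make_record("y", age = NA))
  expect_error(predict_cohort(allna, ng), "no scoreable records")
})

test_that("raising a non-decreasing variable never lowers score or risk", {
  ng <- test_nomogram()
  base <- make_record("m")
  set.seed(3)
  for (i in 1:25) {
    rec <- make_record("m", age = runif(1, 25, 95),
                       heart_rate = runif(1, 40, 130),
                       creatinine = runif(1, 30, 250))
    bumped <- rec
    bumped$age <- rec$age + runif(1, 0, 30)        # age points non-decreasing
    expect_gte(grace_score(bumped, ng), grace_score(rec, ng))
    expect_gte(score_to_risk(grace_score(bumped, ng), ng),
               score_to_risk(grace_score(rec, ng), ng))
  }
})

test_that("nomogram config files round-trip through JSON and YAML", {
  ng <- test_nomogram()
  spec <- list(
    name = "roundtrip",
    variables = lapply(ng$variables, function(v) v),
    score_to_risk = ng$score_to_risk
  )
  jpath <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(spec, jpath, auto_unbox = TRUE, digits = NA)
  from_json <- read_nomogram(jpath)
  ypath <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(spec, ypath)
  from_yaml <- read_nomogram(ypath)
  cohort <- small_synthetic_cohort(n = 40, seed = 2)
  expect_equal(grace_score(cohort, from_json), grace_score(cohort, ng))
  expect_equal(grace_score(cohort, from_yaml), grace_score(cohort, ng))
  expect_error(read_nomogram(sub("yaml$", "txt", ypath)), "not found")
})

test_that("the shipped default table loads, validates and is monotone", {
  ng <- default_nomogram()
  expect_s3_class(ng, "nomogram")
  expect_setequal(names(ng$variables),
                  c("age", "heart_rate", "systolic_bp", "creatinine",
                    "diuretic_in_hospital", "cardiac_arrest", "st_deviation",
                    "elevated_markers"))
  grid <- seq(0, 400, by = 1)
  expect_true(all(diff(score_to_risk(grid, ng)) >= 0))
})

test_that("the optional interpolation mode scores between breakpoints", {
  ng <- test_nomogram()
  # default step function is unchanged
  expect_equal(points_for_variable("age", 65, ng), 10)
  # linear mode: halfway between the 60- and 80-point anchors
  expect_equal(points_for_variable("age", 70, ng, interpolate = TRUE), 15)
  expect_equal(points_for_variable("age", 30, ng, interpolate = TRUE), 0)  # clamp
  # the total is still the sum of per-variable (interpolated) points
  rec <- make_record("i", age = 70)
  expected <- Reduce(`+`, lapply(names(ng$variables), function(nm) {
    points_for_variable(nm, rec[[nm]], ng, interpolate = TRUE)
  }))
  expect_equal(grace_score(rec, ng, interpolate = TRUE), expected)
})
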