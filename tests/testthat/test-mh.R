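test_that("decile assignment gives equal-count bins with stable tie order", {
  expect_equal(assign_deciles(seq(0.01, 0.10, by = 0.01)), 1:10)
  r20 <- runif(20)
  expect_equal(as.vector(table(assign_deciles(r20))), rep(2L, 10))
  expect_error(assign_deciles(runif(9)), "at least 10")

  # heavy ties: equal bins, agreement with an independent rank-sort oracle
  set.seed(1)
  r <- c(rep(0.05, 600), runif(400))
  dec <- assign_deciles(r)
  expect_equal(as.vector(table(dec)), rep(100L, 10))
  expect_equal(dec, oracle_deciles(r))

  # order-preserving across distinct values
  set.seed(2)
  x <- runif(1000)
  d <- assign_deciles(x)
  expect_true(all(d[order(x)] == cummax(d[order(x)])))
})

test_that("stratum tables tally correctly and conserve totals", {
  dec <- c(1, 1, 2, 2)
  grp <- c(TRUE, FALSE, TRUE, FALSE)
  out <- c(TRUE, FALSE, FALSE, TRUE)
  st <- stratum_tables(dec, grp, out)
  expect_equal(st$a, c(1, 0))
  expect_equal(st$n1, c(1, 1))
  expect_equal(st$b, c(0, 1))
  expect_equal(st$n0, c(1, 1))
  expect_equal(st$N, c(2, 2))

  # degenerate single-group stratum
  st1 <- stratum_tables(c(1, 1), c(TRUE, TRUE), c(TRUE, FALSE))
  expect_equal(st1$n0, 0)
  expect_equal(st1$a, 1)

  # conservation of deaths on a larger random input
  set.seed(8)
  dec <- sample(1:10, 500, replace = TRUE)
  grp <- runif(500) < 0.3
  out <- runif(500) < 0.2
  st <- stratum_tables(dec, grp, out)
  expect_equal(sum(st$a + st$b), sum(out))
  expect_equal(sum(st$N), 500)
})

test_that("the pooled risk ratio matches its defining sums", {
  # single stratum reduces to the crude risk ratio
  single <- data.frame(a = 10, n1 = 100, b = 5, n0 = 100)
  expect_equal(mh_pooled_rr(single)$rr, oracle_crude_rr(10, 100, 5, 100))
  expect_equal(mh_pooled_rr(single)$rr, 2)

  # homogeneous strata pool to the common within-stratum RR
  homog <- data.frame(a = c(10, 4), n1 = c(100, 20), b = c(5, 10),
                      n0 = c(100, 100))
  expect_equal(mh_pooled_rr(homog)$rr, 2)

  # two-stratum worked example, frozen from direct evaluation of the sums:
  # num = 8*100/140 + 30*50/110, den = 10*40/140 + 5*60/110 -> 1490/430
  two <- data.frame(a = c(8, 30), n1 = c(40, 60), b = c(10, 5),
                    n0 = c(100, 50))
  expect_equal(mh_pooled_rr(two)$rr, 1490 / 430, tolerance = 1e-12)

  # invariant under stratum reordering
  expect_equal(mh_pooled_rr(two[2:1, ])$rr, mh_pooled_rr(two)$rr)
  expect_equal(mh_pooled_rr(two[2:1, ])$ci_low, mh_pooled_rr(two)$ci_low)
})

test_that("confidence interval brackets the estimate and covers the null case", {
  # identical risks in both groups: RR = 1 and the CI contains 1
  eq <- data.frame(a = c(20, 40), n1 = c(200, 200), b = c(30, 60),
                   n0 = c(300, 300))
  res <- mh_pooled_rr(eq)
  expect_equal(res$rr, 1)
  expect_lt(res$ci_low, 1)
  expect_gt(res$ci_high, 1)
  expect_true(res$ci_low <= res$rr && res$rr <= res$ci_high)
})

test_that("degenerate stratum sets are handled as specified", {
  empty_group <- data.frame(a = c(5, 3), n1 = c(50, 30), b = c(4, 0),
                            n0 = c(60, 0))
  res <- mh_pooled_rr(empty_group)
  expect_equal(res$n_strata_dropped, 1)
  expect_equal(res$n_strata_used, 1)

  expect_error(mh_pooled_rr(data.frame(a = 5, n1 = 50, b = 0, n0 = 60)),
               "no deaths among the unexposed")
  expect_error(mh_pooled_rr(data.frame(a = 1, n1 = 10, b = 0, n0 = 0)),
               "no usable strata")
  expect_error(mh_pooled_rr(data.frame(a = 11, n1 = 10, b = 1, n0 = 10)),
               "invalid stratum counts")
})

test_that("a positive subgroup offset is recovered as RR > 1 with CI excluding 1", {
  cohort <- small_synthetic_cohort(n = 30000, seed = 120)
  cfg <- generator_config(n = 30000, seed = 120)
  copd <- identify_copd(cohort)
  # predictions from the generator's own no-COPD linear predictor
  cfg0 <- cfg
  cfg0$copd_log_odds_offset <- 0
  risk <- implied_outcome_probability(cohort, cfg0)
  res <- mh_pooled_rr(stratum_tables(assign_deciles(risk), copd, cohort$died_6m))
  expect_gt(res$rr, 1)
  expect_gt(res$ci_low, 1)
})

test_that("observed matches predicted per decile when outcomes are drawn from predictions", {
  set.seed(33)
  n <- 40000
  risk <- plogis(rnorm(n, -2.2, 1))
  grp <- runif(n) < 0.15
  out <- runif(n) < risk
  tab <- observed_vs_predicted_by_decile(risk, out, grp)
  expect_equal(nrow(tab), 10)
  for (k in 1:10) {
    n_k <- tab$n[k]
    p_k <- tab$mean_predicted[k]
    se <- sqrt(p_k * (1 - p_k) / n_k)
    pooled_obs <- (tab$observed_non_group[k] * sum(!grp & assign_deciles(risk) == k) +
                   tab$observed_group[k] * sum(grp & assign_deciles(risk) == k)) / n_k
    expect_lt(abs(pooled_obs - p_k), 4 * se)
  }

  # absence is a missing marker, never zero
  tiny_tab <- observed_vs_predicted_by_decile(seq(0.01, 0.1, 0.01),
                                              rep(FALSE, 10), rep(FALSE, 10))
  expect_true(all(is.na(tiny_tab$observed_group)))
  expect_true(all(tiny_tab$observed_non_group == 0))
})

test_that("band-level observed mortality sits inside each band's risk interval", {
  set.seed(44)
  n <- 60000
  risk <- pmin(runif(n, 0, 0.2), 0.999)
  out <- runif(n) < risk
  grp <- runif(n) < 0.2
  tab <- observed_by_band(risk, out, grp, risk_bands())
  expect_equal(as.character(tab$band), c("low", "moderate", "high"))
  expect_lt(tab$observed_non_group[1], 0.03 + 0.003)
  expect_gt(tab$observed_non_group[3], 0.06 - 0.003)
  expect_true(tab$observed_non_group[2] > 0.02 && tab$observed_non_group[2] < 0.07)

  # single dead record lands as 100% in its band/group cell
  one <- observed_by_band(0.5, TRUE, TRUE)
  expect_equal(one$observed_group[3], 1)
  expect_true(is.na(one$observed_non_group[3]))
  expect_true(is.na(one$observed_group[1]))  # empty band: missing marker
})
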