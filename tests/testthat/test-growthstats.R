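test_that("the paired t statistic matches hand arithmetic and the t.test oracle", {
  r <- pairedTtest(c(1, 2, 3), c(2, 2, 5))
  expect_equal(r@tStatistic, sqrt(3), tolerance = 1e-12)
  expect_identical(r@degreesOfFreedom, 2)
  expect_equal(r@meanDifference, 1)
  expect_equal(r@semDifference, 1 / sqrt(3), tolerance = 1e-12)
  expect_equal(r@pValue, 2 * (1 - stats::pt(sqrt(3), 2)), tolerance = 1e-12)

  set.seed(1)
  for (i in 1:20) {
    n <- sample(3:30, 1)
    x <- stats::rnorm(n)
    y <- x + stats::rnorm(n, 0.3, 0.7)
    ours <- pairedTtest(x, y)
    ref <- stats::t.test(y, x, paired = TRUE)
    expect_equal(ours@tStatistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours@pValue, ref$p.value, tolerance = 1e-10)
    # identity: paired test equals one-sample test of the differences
    one <- stats::t.test(y - x)
    expect_equal(ours@tStatistic, unname(one$statistic), tolerance = 1e-10)
  }
})

test_that("degenerate paired inputs are rejected", {
  expect_error(pairedTtest(c(1, 2), c(1, 2, 3)), "equal length")
  expect_error(pairedTtest(c(1, 2, 3), c(1, 2, 3)), "degenerate variance")
  expect_error(pairedTtest(c(1, 2, 3), c(3, 4, 5)), "degenerate variance")
  expect_error(pairedTtest(1, 2), "at least 2")
})

test_that("two-sample tests follow Welch and pooled conventions", {
  same <- twosampleTtest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same@tStatistic, 0)
  expect_equal(same@pValue, 1)

  shifted <- twosampleTtest(c(1, 2, 3) + 10, c(1, 2, 3))
  expect_lt(shifted@pValue, 0.01)

  # Welch equals pooled when group sizes and variances coincide
  a <- c(1, 2, 3, 4)
  b <- c(2, 3, 4, 5)
  w <- twosampleTtest(a, b)
  p <- twosampleTtest(a, b, equalVariance = TRUE)
  expect_equal(w@tStatistic, p@tStatistic, tolerance = 1e-12)
  expect_equal(w@degreesOfFreedom, p@degreesOfFreedom, tolerance = 1e-12)

  set.seed(2)
  x <- stats::rnorm(12, 1, 1)
  y <- stats::rnorm(20, 0, 2)
  ours <- twosampleTtest(x, y)
  ref <- stats::t.test(x, y)
  expect_equal(ours@tStatistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(ours@degreesOfFreedom, unname(ref$parameter),
               tolerance = 1e-10)
  expect_equal(ours@pValue, ref$p.value, tolerance = 1e-10)
  expect_error(twosampleTtest(c(1, 1), c(2, 2)), "degenerate")
})

test_that("group summaries report mean, SEM and gainer percentage", {
  s <- summarizeGroup(c(rep(0.1, 8), rep(-0.05, 7)))
  expect_identical(s@n, 15L)
  expect_identical(s@gainerPercent, 53.33)
  expect_equal(s@sem, stats::sd(c(rep(0.1, 8), rep(-0.05, 7))) / sqrt(15))
  expect_identical(summarizeGroup(rep(0.2, 10))@gainerPercent, 100)
  expect_true(is.na(summarizeGroup(5)@sem))
  expect_error(summarizeGroup(numeric()), "empty")
})

test_that("the t CDF agrees with the reference implementation to 1e-8", {
  g <- expand.grid(t = seq(-8, 8, by = 0.25), df = c(1, 2, 3, 5, 10, 14, 29,
                                                     50, 200))
  expect_lt(max(abs(soleVision:::tCdf(g$t, g$df) - stats::pt(g$t, g$df))),
            1e-8)
})

test_that("p-values are calibrated under the null", {
  set.seed(99)
  p <- replicate(1000, {
    x <- stats::rnorm(15)
    pairedTtest(x, x + stats::rnorm(15, 0, 0.1))@pValue
  })
  rate <- mean(p < 0.05)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})

test_that("the calibrated experimental growth effect is detected in nearly every cohort", {
  rejected <- vapply(1:200, function(s) {
    e <- generateGrowthCohort(seed = s)
    e <- e[e$group == "EXP", ]
    pairedTtest(e$weight_t0_kg, e$weight_t1_kg)@pValue < 0.05
  }, logical(1))
  expect_gte(mean(rejected), 0.95)
})

test_that("analyzeCohort assembles summaries and tests per group", {
  co <- generateGrowthCohort(seed = 12)
  res <- analyzeCohort(co)
  expect_setequal(names(res$groups), c("CTRL", "EXP"))
  expect_s4_class(res$groups$EXP$paired, "PairedTestResult")
  expect_s4_class(res$increment_comparison, "TwoSampleTestResult")
  expect_identical(res$increment_comparison@method, "welch")
  expect_identical(res$groups$CTRL$t0@n, 15L)
  flat <- cohortStatsAsList(res)
  expect_true(is.numeric(flat$increment_comparison$p))
})
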