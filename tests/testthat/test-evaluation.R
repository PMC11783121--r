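test_that("prediction metrics reproduce hand-computed values", {
  perfect <- prediction_metrics(c(10, 20, 30), c(10, 20, 30))
  expect_equal(perfect[c("mape", "relative_bias", "rmse")],
               list(mape = 0, relative_bias = 0, rmse = 0))
  expect_equal(perfect$f80_125, 100)

  single <- prediction_metrics(12, 16)
  expect_equal(single$mape, 25)
  expect_equal(single$relative_bias, -25) # negative = underprediction
  expect_equal(single$rmse, 4)
  expect_equal(single$f80_125, 0)

  triple <- prediction_metrics(c(20, 9, 15), c(16, 12, 15))
  expect_equal(triple$mape, 25)            # median of 25, 25, 0
  expect_equal(triple$relative_bias, 0)    # median of 25, -25, 0
  expect_equal(triple$rmse, sqrt(25 / 3), tolerance = 1e-12)
  expect_equal(triple$f80_125, 100 * 2 / 3)
})

test_that("mean centring differs from the default median where it should", {
  p <- c(20, 9, 15); o <- c(16, 12, 15)
  expect_equal(prediction_metrics(p, o, center = "mean")$mape, 50 / 3)
  expect_equal(prediction_metrics(p, o, center = "mean")$relative_bias, 0)
  expect_error(prediction_metrics(numeric(0), numeric(0)), "no prediction")
  expect_error(prediction_metrics(1, 0), "> 0")
})

test_that("F80-125 is invariant to common scaling and inclusive at its bounds", {
  set.seed(31)
  p <- exp(rnorm(200)); o <- exp(rnorm(200))
  expect_equal(prediction_metrics(p, o)$f80_125,
               prediction_metrics(3.7 * p, 3.7 * o)$f80_125)
  expect_equal(prediction_metrics(c(0.8, 1.25), c(1, 1))$f80_125, 100)
})

test_that("the uncorrected Pearson statistic matches the textbook formula and oracle", {
  # equal proportions -> 0; Yates strictly smaller on non-degenerate tables
  expect_equal(chisq_2x2(10, 10, 20, 20)$statistic, 0)
  expect_lt(chisq_2x2(8, 3, 4, 9, correct = TRUE)$statistic,
            chisq_2x2(8, 3, 4, 9)$statistic)
  for (t in random_tables(1000, seed = 32)) {
    a <- t[1, 1]; b <- t[1, 2]; c <- t[2, 1]; d <- t[2, 2]; n <- sum(t)
    brute <- n * (a * d - b * c)^2 /
      ((a + b) * (c + d) * (a + c) * (b + d))
    expect_equal(chisq_2x2(t)$statistic, brute)
    # invariant under swapping both rows and both columns
    expect_equal(chisq_2x2(t[2:1, 2:1])$statistic, chisq_2x2(t)$statistic)
  }
  # independent implementation
  for (t in random_tables(50, seed = 33)) {
    expect_equal(chisq_2x2(t)$statistic,
                 unname(suppressWarnings(
                   chisq.test(t, correct = FALSE)$statistic)))
    expect_equal(chisq_2x2(t, correct = TRUE)$statistic,
                 unname(suppressWarnings(chisq.test(t)$statistic)))
  }
  expect_error(chisq_2x2(0, 0, 5, 5), "margin")
})

test_that("Fisher's exact p equals the hypergeometric enumeration", {
  # enumeration for the 40 mg comparison: 0/5 below vs 21/24 below
  t <- matrix(c(0, 5, 21, 3), 2, 2, byrow = TRUE)
  p_enum <- {
    m <- 21; n2 <- 8; k <- 5
    xs <- max(0, k - n2):min(k, m)
    pr <- dhyper(xs, m, n2, k)
    sum(pr[pr <= dhyper(0, m, n2, k) * (1 + 1e-7)])
  }
  expect_equal(fisher_2x2(t), p_enum)
  expect_equal(fisher_2x2(t), 0.0004715591, tolerance = 1e-6)
  expect_lt(fisher_2x2(t), 0.001)
  expect_equal(fisher_2x2(1, 1, 1, 1), 1)
  for (t in random_tables(300, seed = 34, lambda_max = 12)) {
    expect_equal(fisher_2x2(t), fisher.test(t)$p.value, tolerance = 1e-10)
    expect_gte(fisher_2x2(t), 0)
    expect_lte(fisher_2x2(t), 1)
  }
})

test_that("analytic power is monotone in n and the sample-size search inverts it", {
  ns <- seq(20, 400, by = 10)
  pow <- analytic_power(0.78, 0.90, 443, ns)
  expect_true(all(diff(pow) > 0))
  n_req <- required_sample_size(0.78, 0.90, n_control = 443)
  expect_gte(analytic_power(0.78, 0.90, 443, n_req), 0.80)
  expect_lt(analytic_power(0.78, 0.90, 443, n_req - 1), 0.80)
  expect_error(required_sample_size(0.8, 0.8, 443), "no effect")
  expect_error(empirical_power(0.8, 0.8, 443, 106), "no effect")
})

test_that("empirical power agrees with the analytic approximation and saturates", {
  reps <- 4000
  emp <- empirical_power(0.78, 0.90, 443, 106, reps = reps, seed = 35)
  ana <- analytic_power(0.78, 0.90, 443, 106)
  mc_se <- sqrt(ana * (1 - ana) / reps)
  expect_lt(abs(emp - ana), 2 * mc_se + 0.01)
  expect_gt(empirical_power(0.05, 0.95, 400, 400, reps = 1000, seed = 36),
            0.999)
})

test_that("MCID comparisons are strict and two-sided", {
  expect_false(mcid_compare(64.8, 61.3, mcid = 4.4))  # diff -3.5
  expect_false(mcid_compare(82.8, 87.6, mcid = 6.98)) # diff +4.8
  expect_false(mcid_compare(60, 64.5, mcid = 4.5))    # exactly at the MCID
  expect_true(mcid_compare(60, 64.51, mcid = 4.5))
  expect_true(mcid_compare(60, 55.5, mcid = 4.4))
  expect_error(mcid_compare(1, 2, mcid = 0), "mcid")
})

test_that("attainment tables count sub-therapeutic patients per group", {
  obs <- c(18, 15, 20, 3, 16)
  grp <- factor(c("a", "a", "b", "b", "c"), levels = c("a", "b", "c", "empty"))
  tab <- attainment_table(obs, grp)
  expect_identical(tab$n_below, c(1L, 1L, 0L, 0L))
  expect_identical(tab$n_total, c(2L, 2L, 1L, 0L))
  expect_equal(tab$pct_below, c(50, 50, 0, NA))
  all_above <- attainment_table(c(16, 17), c("x", "y"))
  expect_identical(all_above$n_below, c(0L, 0L))
})

test_that("percentages round half up to one decimal", {
  expect_equal(round_half_up(91.45, 1), 91.5)
  expect_equal(round_half_up(-91.45, 1), -91.5)
  expect_equal(round_half_up(0.125, 2), 0.13)
})
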