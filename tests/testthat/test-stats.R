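make_results <- function(log10s, sample_type = "soil", censoring = NULL,
                         ...) {
  meta <- list(...)
  if (is.null(censoring)) censoring <- rep("interval_ok", length(log10s))
  tibble::tibble(
    sample_id = sprintf("s%03d", seq_along(log10s)),
    sample_type = sample_type,
    log10_value = log10s,
    censoring = censoring,
    !!!meta
  )
}

test_that("stratum summaries give sample mean, SD and percent positive", {
  res <- make_results(c(2.0), censoring = "interval_ok")
  out <- summarize_concentrations(res)
  expect_equal(out$mean_log10, 2.0)
  expect_true(is.na(out$sd_log10))  # undefined at n = 1
  res <- make_results(c(1, 3), censoring = c("left", "interval_ok"))
  out <- summarize_concentrations(res)
  expect_equal(out$mean_log10, 2.0)
  expect_equal(out$sd_log10, sd(c(1, 3)))  # sample SD, 1.414
  expect_equal(out$percent_positive, 50)
  # permutation invariance
  res2 <- res[2:1, ]
  expect_equal(summarize_concentrations(res2)$mean_log10, out$mean_log10)
})

test_that("grouped summaries stratify within sample type", {
  res <- make_results(c(1, 2, 3, 7), category = c("low_income", "low_income",
                                                  "high_income", "high_income"))
  out <- summarize_concentrations(res, "category")
  expect_identical(nrow(out), 2L)
  expect_equal(out$mean_log10[out$category == "low_income"], 1.5)
  expect_equal(out$mean_log10[out$category == "high_income"], 5)
})

test_that("pooled category mean equals mean of equal-size neighborhood means", {
  set.seed(31)
  res <- make_results(rnorm(40, 2, 1),
                      category = "low_income",
                      neighborhood = rep(c("A", "B", "C", "D"), each = 10))
  by_cat <- summarize_concentrations(res, "category")
  by_nb <- summarize_concentrations(res, "neighborhood")
  expect_equal(by_cat$mean_log10, mean(by_nb$mean_log10))
})

test_that("stratum contrast is the difference in means with pooled-SE CI", {
  set.seed(99)
  res <- make_results(c(rnorm(40, 3, 1), rnorm(40, 2, 1)),
                      category = rep(c("low_income", "high_income"), each = 40))
  out <- compare_strata(res, "category", "low_income", "high_income")
  expect_equal(out$mean_difference, out$mean_a - out$mean_b)
  # CI from lm's pooled SE with the 1.96 multiplier
  fit <- lm(log10_value ~ category, data = res)
  se <- sqrt(diag(vcov(fit)))[2]
  expect_equal(out$ci_high - out$ci_low, unname(2 * 1.96 * se),
               tolerance = 1e-10)
  expect_true(out$ci_low <= out$mean_difference &
                out$mean_difference <= out$ci_high)
  # antisymmetry of the contrast
  rev <- compare_strata(res, "category", "high_income", "low_income")
  expect_equal(rev$mean_difference, -out$mean_difference)
  # shift equivariance: +c on stratum A shifts the difference by +c
  res_shift <- res
  idx <- res_shift$category == "low_income"
  res_shift$log10_value[idx] <- res_shift$log10_value[idx] + 0.7
  out_shift <- compare_strata(res_shift, "category", "low_income",
                              "high_income")
  expect_equal(out_shift$mean_difference, out$mean_difference + 0.7)
})

test_that("identical strata give a null contrast whose CI spans zero", {
  res <- make_results(rep(c(1, 2, 3), 2),
                      category = rep(c("low_income", "high_income"), each = 3))
  out <- compare_strata(res, "category", "low_income", "high_income")
  expect_equal(out$mean_difference, 0)
  expect_lt(out$ci_low, 0)
  expect_gt(out$ci_high, 0)
  expect_false(out$significant)
})

test_that("undersized strata are suppressed with a warning", {
  res <- make_results(c(1, 2, 3), category = c("low_income", "high_income",
                                               "high_income"))
  expect_warning(out <- compare_strata(res, "category", "low_income",
                                       "high_income"),
                 "suppressed")
  expect_true(is.na(out$mean_difference))
})

test_that("t and rank-sum tests agree with their reference values", {
  out <- feces_proximity_test(c(1, 2, 3, 1, 2, 3),
                              rep(c(TRUE, FALSE), each = 3))
  expect_equal(out$statistic[out$test == "t"], 0)
  expect_equal(out$p_value[out$test == "t"], 1)
  # complete separation: W equals its enumerated value 9, exact p = 2/20
  out <- feces_proximity_test(c(4, 5, 6, 1, 2, 3),
                              rep(c(TRUE, FALSE), each = 3))
  expect_equal(out$statistic[out$test == "wilcoxon"], 9)
  expect_equal(out$p_value[out$test == "wilcoxon"], 0.1)
  # fully tied inputs are handled, not NaN
  out <- feces_proximity_test(rep(2, 6), rep(c(TRUE, FALSE), each = 3))
  expect_equal(out$p_value[out$test == "wilcoxon"], 1)
  expect_error(feces_proximity_test(1:4, rep(TRUE, 4)), "two levels")
})

test_that("significance tiers follow the 0.05/0.01/0.001 annotation levels", {
  expect_identical(mpnenv:::significance_tier(c(0.2, 0.04, 0.009, 1e-5)),
                   c("ns", "p<0.05", "p<0.01", "p<0.001"))
})
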