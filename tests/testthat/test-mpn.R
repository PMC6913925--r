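test_that("log-likelihood matches the binomial-Poisson formula", {
  g <- tray_geometry()
  # frozen direct evaluation of the formula at lambda = 0.0101, (1 large, 0 small)
  expect_equal(tray_log_likelihood(0.0101, 1, 0, g), -4.97592246271,
               tolerance = 1e-9)
  # random patterns against the independently written oracle
  set.seed(42)
  for (i in 1:20) {
    tr <- random_tray(g)
    lam <- runif(1, 1e-4, 5)
    expect_equal(
      tray_log_likelihood(lam, tr$p_large, tr$p_small, g),
      oracle_loglik(lam, tr$p_large, tr$p_small, g$n_large, g$n_small,
                    g$v_large, g$v_small),
      tolerance = 1e-10
    )
  }
})

test_that("all-negative tray log-likelihood is -lambda times total volume", {
  g <- tray_geometry()
  v_tot <- 49 * 1.86 + 48 * 0.186
  lams <- c(0.01, 0.5, 2, 10)
  expect_equal(tray_log_likelihood(lams, 0, 0, g), -lams * v_tot)
  # strictly decreasing in lambda
  expect_true(all(diff(tray_log_likelihood(lams, 0, 0, g)) < 0))
})

test_that("likelihood of a positive well vanishes as lambda -> 0+", {
  ll <- tray_log_likelihood(c(1e-12, 1e-9, 1e-6), 1, 0)
  expect_true(all(diff(ll) > 0))
  expect_lt(ll[1], -20)  # diverges to -Inf in the limit
})

test_that("lambda domain is enforced", {
  expect_error(tray_log_likelihood(0, 1, 0), "positive")
  expect_error(tray_log_likelihood(-1, 1, 0), "positive")
  expect_error(mpn_estimate(50, 0), "p_large")
  expect_error(mpn_estimate(1, 49), "p_small")
})

test_that("censoring classification follows the well pattern", {
  expect_identical(mpn_estimate(0, 0)$status, "nondetect")
  expect_true(is.na(mpn_estimate(0, 0)$mpn))
  expect_identical(mpn_estimate(49, 48)$status, "overrange")
  expect_true(is.na(mpn_estimate(49, 48)$mpn))
  expect_identical(mpn_estimate(1, 0)$status, "quantifiable")
  # all-positive is relative to the geometry's own well count
  g1 <- tray_geometry(n_large = 49, n_small = 0)
  expect_identical(mpn_estimate(49, 0, g1)$status, "overrange")
  expect_identical(mpn_estimate(48, 0, g1)$status, "quantifiable")
  expect_true(is.finite(mpn_estimate(48, 0, g1)$mpn))
})

test_that("single positive large well estimates ~1 MPN per 100 mL", {
  est <- mpn_estimate(1, 0)
  expect_equal(est$mpn, 1.0, tolerance = 0.02)
  # closed-form score equation: v_L * q/(1-q) = total negative volume
  neg_vol <- 48 * 1.86 + 48 * 0.186
  lam_closed <- log1p(1.86 / neg_vol) / 1.86
  expect_equal(est$lambda, lam_closed, tolerance = 1e-7)
})

test_that("MLE matches the grid-search oracle on random trays/geometries", {
  set.seed(2024)
  n_checked <- 0L
  for (i in 1:200) {
    g <- random_geometry()
    tr <- random_tray(g)
    est <- mpn_estimate(tr$p_large, tr$p_small, g)
    lam_oracle <- oracle_mle(tr$p_large, tr$p_small, g$n_large, g$n_small,
                             g$v_large, g$v_small)
    expect_equal(est$lambda, lam_oracle, tolerance = 1e-4)
    n_checked <- n_checked + 1L
  }
  expect_identical(n_checked, 200L)
})

test_that("single-well-class MLE has the closed form -log((n-p)/n)/v", {
  for (p in c(1, 10, 25, 48)) {
    g <- tray_geometry(n_large = 49, n_small = 0, v_large = 1.86)
    est <- mpn_estimate(p, 0, g)
    expect_equal(est$lambda, -log((49 - p) / 49) / 1.86, tolerance = 1e-7)
  }
})

test_that("adding a positive well never decreases the MPN", {
  g <- tray_geometry()
  mpn_at <- function(pl, ps) mpn_estimate(pl, ps, g)$mpn
  set.seed(7)
  for (i in 1:25) {
    pl <- sample(0:47, 1); ps <- sample(0:46, 1)
    if (pl + ps == 0) next
    base <- mpn_at(pl, ps)
    expect_gte(mpn_at(pl + 1, ps), base)
    expect_gte(mpn_at(pl, ps + 1), base)
  }
})

test_that("scaling all well volumes by c divides the per-mL MLE by c", {
  for (cc in c(0.5, 2, 10)) {
    g1 <- tray_geometry()
    g2 <- tray_geometry(v_large = 1.86 * cc, v_small = 0.186 * cc)
    l1 <- mpn_estimate(20, 5, g1)$lambda
    l2 <- mpn_estimate(20, 5, g2)$lambda
    expect_equal(l2, l1 / cc, tolerance = 1e-6)
  }
})

test_that("profile-likelihood interval brackets the MLE and nests by level", {
  est <- mpn_estimate(1, 0)
  ci <- mpn_confint(1, 0)
  expect_lt(ci[["low"]], est$mpn)
  expect_gt(ci[["high"]], est$mpn)
  expect_true(ci[["low"]] < 1.0 && ci[["high"]] > 1.0)
  # grid check of the likelihood-ratio set on the lambda scale
  g <- tray_geometry()
  crit <- qchisq(0.95, 1) / 2
  ll_hat <- tray_log_likelihood(est$lambda, 1, 0, g)
  grid <- exp(seq(log(1e-6), log(1), length.out = 3000))
  inside <- grid[ll_hat - tray_log_likelihood(grid, 1, 0, g) <= crit]
  expect_equal(ci[["low"]], 100 * min(inside), tolerance = 5e-3)
  expect_equal(ci[["high"]], 100 * max(inside), tolerance = 5e-3)

  # level = 0 collapses to the MLE; wider level strictly contains narrower
  ci0 <- mpn_confint(1, 0, level = 0)
  expect_equal(as.numeric(ci0), rep(est$mpn, 2))
  ci99 <- mpn_confint(1, 0, level = 0.99)
  expect_lt(ci99[["low"]], ci[["low"]])
  expect_gt(ci99[["high"]], ci[["high"]])
})

test_that("censored trays get flagged one-sided bounds", {
  lo <- mpn_confint(0, 0)
  expect_identical(attr(lo, "one_sided"), "upper")
  expect_identical(lo[["low"]], 0)
  # upper bound: lambda with 2*(0 - (-lambda V)) = chisq crit
  v_tot <- 49 * 1.86 + 48 * 0.186
  expect_equal(lo[["high"]], 100 * qchisq(0.95, 1) / 2 / v_tot,
               tolerance = 1e-8)
  hi <- mpn_confint(49, 48)
  expect_identical(attr(hi, "one_sided"), "lower")
  expect_identical(hi[["high"]], Inf)
  expect_gt(hi[["low"]], 0)
})
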