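# REML tau^2, pooling, heterogeneity and subgroup analysis.

test_that("estimate_tau2 is 0 for identical effects and matches the grid oracle", {
  same <- data.frame(lnr = rep(0.3, 6), variance = runif(6, 0.1, 0.9))
  expect_equal(estimate_tau2(same), 0)
  # frozen grid-maximization value for the spread-out, tiny-variance case
  spread <- data.frame(lnr = c(-0.2, -0.1, 0, 0.1, 0.2),
                       variance = rep(0.001, 5))
  expect_equal(estimate_tau2(spread), 0.024, tolerance = 1e-4)
  # random small instances against the brute-force restricted likelihood
  set.seed(31)
  for (i in 1:10) {
    inst <- random_instance(sample(4:10, 1))
    expect_lt(abs(estimate_tau2(inst) -
                    oracle_reml_grid(inst$lnr, inst$variance)), 1e-4)
  }
})

test_that("pool_effects weights by 1/(v + tau2) with normal-theory intervals", {
  one <- data.frame(lnr = 0.5, variance = 0.3)
  s <- pool_effects(one, tau2 = 0.1)
  expect_equal(s$mu_hat, 0.5)
  expect_equal(s$se, sqrt(0.4))
  # uniform weights reduce to the arithmetic mean
  eq <- data.frame(lnr = c(0.1, 0.4, 0.7), variance = rep(0.2, 3))
  expect_equal(pool_effects(eq, tau2 = 0)$mu_hat, 0.4)
  # hand-computed two-study weighted mean: weights 1 and 3
  two <- data.frame(lnr = c(0, log(4)), variance = c(1, 1 / 3))
  expect_equal(pool_effects(two, tau2 = 0)$mu_hat, log(4) * 3 / 4)
  # ordering and weight-scaling invariance; bounds within input range
  set.seed(41)
  for (i in 1:10) {
    inst <- random_instance(8)
    a <- pool_effects(inst, tau2 = 0.02)
    b <- pool_effects(inst[sample(8), ], tau2 = 0.02)
    expect_equal(a$mu_hat, b$mu_hat)
    expect_gte(a$mu_hat, min(inst$lnr))
    expect_lte(a$mu_hat, max(inst$lnr))
    expect_true(a$ci_low <= a$mu_hat && a$mu_hat <= a$ci_high)
  }
  # tau2 -> large tends to the unweighted mean; tau2 = 0 is the FE mean
  inst <- random_instance(12)
  expect_equal(pool_effects(inst, tau2 = 1e8)$mu_hat, mean(inst$lnr),
               tolerance = 1e-6)
  w <- 1 / inst$variance
  expect_equal(pool_effects(inst, tau2 = 0)$mu_hat,
               sum(w * inst$lnr) / sum(w))
})

test_that("heterogeneity computes Q, df, I2 with truncation, and chi-square p", {
  same <- data.frame(lnr = rep(0.2, 5), variance = runif(5, 0.2, 0.5))
  h <- heterogeneity(same)
  expect_equal(h$q_total, 0)
  expect_equal(h$i2, 0)
  # I2 truncates at 0 whenever Q <= df
  set.seed(51)
  homog <- data.frame(lnr = rnorm(30, 0.3, 0.05), variance = rep(1, 30))
  h2 <- heterogeneity(homog)
  expect_lte(h2$q_total, h2$df)
  expect_equal(h2$i2, 0)
  # direct substitution: Q = 100, df = 50 -> I2 = 50%
  expect_equal(max(0, 100 - 50) * 100 / 100, 50)
  # scaling all variances leaves the fixed-effect mean unchanged
  inst <- random_instance(15)
  w1 <- 1 / inst$variance
  w2 <- 1 / (9 * inst$variance)
  expect_equal(sum(w1 * inst$lnr) / sum(w1), sum(w2 * inst$lnr) / sum(w2))
  expect_error(heterogeneity(inst[1, , drop = FALSE]), "at least 2")
})

test_that("subgroup_analysis pools a common tau2 and tests Q_between", {
  set.seed(61)
  inst <- random_instance(20)
  # identical study sets in both levels -> no between-level difference
  dup <- rbind(inst, inst)
  sr0 <- subgroup_analysis(dup, rep(c("a", "b"), each = 20))
  expect_lt(sr0$q_between, 1e-10)
  expect_equal(sr0$df_between, 1L)
  # separated levels: means 2 apart with tiny variances
  sep <- data.frame(lnr = c(rnorm(10, 0, 0.01), rnorm(10, 2, 0.01)),
                    variance = rep(1e-4, 20))
  sr1 <- subgroup_analysis(sep, rep(c("lo", "hi"), each = 10))
  expect_lt(sr1$p_between, 0.001)
  expect_equal(nrow(sr1$levels), 2L)
  expect_error(subgroup_analysis(inst, rep("one", 20)), "levels")
})

test_that("stress-pattern subgroup contrast is detected with adequate power", {
  # stressed mean 0.54 vs unstressed 0.33 on the lnR scale, k = 300/level;
  # scaled down to 20 replicates to stay within the test budget
  set.seed(71)
  hits <- 0L
  reps <- 20L
  for (i in seq_len(reps)) {
    k <- 300L
    v <- nonparametric_variance(sample(3:8, 2 * k, TRUE),
                                sample(3:8, 2 * k, TRUE))
    y <- rnorm(2 * k, rep(c(0.54, 0.33), each = k), sqrt(0.05 + v))
    sr <- subgroup_analysis(data.frame(lnr = y, variance = v),
                            rep(c("stressed", "unstressed"), each = k))
    hits <- hits + (sr$p_between < 0.05)
  }
  expect_gte(hits / reps, 0.95)
})

test_that("chronology_bin maps years onto the seven 5-year periods", {
  expect_equal(as.character(chronology_bin(1980)), "1980-1984")
  expect_equal(as.character(chronology_bin(1999)), "1995-1999")
  expect_equal(as.character(chronology_bin(2014)), "2010-2014")
  expect_equal(nlevels(chronology_bin(1980)), 7L)
  expect_error(chronology_bin(1979))
  expect_error(chronology_bin(2015))
})

test_that("REML non-convergence surfaces the last iterate", {
  set.seed(81)
  inst <- random_instance(6)
  err <- tryCatch(mycometa:::.reml_tau2(inst$lnr, inst$variance, maxit = 1L),
                  mycometa_no_convergence = function(e) e)
  # either converged in one step or raised the classed condition
  if (inherits(err, "mycometa_no_convergence"))
    expect_true(is.numeric(err$tau2_last))
  else expect_true(is.list(err))
})
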