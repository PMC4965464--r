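# Knapp-Hartung meta-regression and its derived quantities.

test_that("fit_meta_regression recovers a noiseless line and rejects degenerate designs", {
  x <- seq(0, 100, length.out = 12)
  y <- 0.25 + 0.004 * x
  es <- data.frame(lnr = y, variance = rep(1e-8, 12))
  fit <- fit_meta_regression(es, data.frame(colonization = x))
  expect_equal(fit$coef$estimate[1], 0.25, tolerance = 1e-6)
  expect_equal(fit$coef$estimate[2], 0.004, tolerance = 1e-6)
  # constant moderator -> rank deficiency naming the column
  expect_error(fit_meta_regression(es, data.frame(flat = rep(3, 12))),
               "flat")
  # duplicated moderator -> rank deficiency
  expect_error(
    fit_meta_regression(es, data.frame(a = x, b = 2 * x)), "collinear")
  expect_error(fit_meta_regression(es[1:2, ], data.frame(x = x[1:2])),
               "k >=")
})

test_that("with zero within-study variance and tau2, fit equals ordinary least squares", {
  set.seed(13)
  x <- runif(20, 0, 10)
  y <- 0.1 + 0.3 * x + rnorm(20, 0, 0.2)
  es <- data.frame(lnr = y, variance = rep(1e-10, 20))
  fit <- fit_meta_regression(es, data.frame(x = x))
  ols <- coef(lm(y ~ x))
  expect_equal(fit$coef$estimate, unname(ols), tolerance = 1e-3)
})

test_that("affine moderator rescaling rescales the slope and preserves its p-value", {
  set.seed(23)
  inst <- random_instance(30)
  x <- runif(30, 0, 100)
  f1 <- fit_meta_regression(inst, data.frame(x = x))
  f2 <- fit_meta_regression(inst, data.frame(x = 5 * x + 7))
  expect_equal(f2$coef$estimate[2], f1$coef$estimate[2] / 5, tolerance = 1e-6)
  expect_equal(f2$coef$p[2], f1$coef$p[2], tolerance = 1e-8)
  expect_equal(f2$tau2, f1$tau2, tolerance = 1e-8)
})

test_that("average_raw_slope back-transforms printed coefficients correctly", {
  expect_equal(round(average_raw_slope(-0.0149, 0.0079, 0, 100), 4), 0.0119)
  expect_equal(round(average_raw_slope(21.8340, -0.0107, 1980, 2014), 4),
               -0.0171)
  # flat fits back-transform flat, sign follows the lnR slope
  expect_equal(average_raw_slope(0.7, 0, 0, 100), 0)
  expect_equal(average_raw_slope(-2, 0, 1980, 2014), 0)
  set.seed(33)
  for (i in 1:20) {
    b <- rnorm(1, 0, 0.05)
    a <- rnorm(1, 0, 0.5)
    expect_equal(sign(average_raw_slope(a, b, 0, 50)), sign(b))
  }
  expect_error(average_raw_slope(0, 1, 5, 5), "exceed")
})

test_that("r2_analog truncates to [0, 100] and is undefined at zero total tau2", {
  expect_equal(r2_analog(0, 0.05), 100)
  expect_equal(r2_analog(0.05, 0.05), 0)
  expect_equal(r2_analog(0.08, 0.05), 0)      # residual exceeding total -> 0
  expect_true(is.na(r2_analog(0, 0)))
  expect_equal(r2_analog(0.02, 0.05), 60)
  # invariant to common scaling of all variance components
  expect_equal(r2_analog(0.02 * 7, 0.05 * 7), r2_analog(0.02, 0.05))
})

test_that("incremental_moderator_test equals the squared-t F test and validates its target", {
  set.seed(43)
  inst <- random_instance(40)
  X <- data.frame(a = runif(40), b = runif(40))
  res <- incremental_moderator_test(inst, X, "a")
  full <- fit_meta_regression(inst, X)
  expect_equal(res$p_test, full$coef$p[full$coef$term == "a"],
               tolerance = 1e-10)
  expect_error(incremental_moderator_test(inst, X, "zz"), "not in")
  X$dup <- X$a
  expect_error(incremental_moderator_test(inst, X, "dup"), "collinear")
})

test_that("cooks_distance flags constructed influence and predicts refit change", {
  # exact fit -> all distances 0
  x <- 1:10
  es <- data.frame(lnr = 0.1 + 0.02 * x, variance = rep(1e-6, 10))
  fit <- fit_meta_regression(es, data.frame(x = x))
  expect_true(all(cooks_distance(fit)$cooks_d < 1e-8))
  # a single far outlier carries the largest distance
  set.seed(53)
  x <- runif(25, 0, 10)
  y <- 0.2 + 0.05 * x + rnorm(25, 0, 0.05)
  y[25] <- 3
  es <- data.frame(lnr = y, variance = rep(0.01, 25),
                   study_id = paste0("s", 1:25))
  fit <- fit_meta_regression(es, data.frame(x = x))
  inf <- cooks_distance(fit)
  expect_equal(which.max(inf$cooks_d), 25L)
  expect_true(inf$flagged[25])
  # removing the max-D study moves the slope more than removing others
  slope_wo <- function(drop) {
    f <- fit_meta_regression(es[-drop, ], data.frame(x = x[-drop]))
    f$coef$estimate[2]
  }
  full_slope <- fit$coef$estimate[2]
  d_max <- abs(slope_wo(25) - full_slope)
  others <- sample(1:24, 5)
  expect_true(all(abs(vapply(others, slope_wo, numeric(1)) - full_slope)
                  <= d_max))
})

test_that("weighted_moderator_correlation recovers known structure", {
  set.seed(63)
  n <- 1000
  a <- rnorm(n)
  b <- rnorm(n)
  w <- runif(n, 0.5, 2)
  wc <- weighted_moderator_correlation(data.frame(a = a, b = b), w)
  expect_equal(diag(wc$r), c(a = 1, b = 1))
  expect_lt(abs(wc$r["a", "b"]), 0.1)
  # correlation -0.3 recovered within 0.1 at n = 500
  n <- 500
  a <- rnorm(n)
  b <- -0.3 * a + sqrt(1 - 0.09) * rnorm(n)
  wc2 <- weighted_moderator_correlation(data.frame(a = a, b = b),
                                        runif(n, 0.5, 2))
  expect_lt(abs(wc2$r["a", "b"] - (-0.3)), 0.1)
  # fewer than 3 complete pairs -> missing cell
  m <- data.frame(a = c(1, 2, 4, NA, NA), b = c(NA, NA, NA, 1, 2),
                  c = c(2, 5, 3, 1, 7))
  wc3 <- weighted_moderator_correlation(m, rep(1, 5))
  expect_true(is.na(wc3$r["a", "b"]))
  expect_false(is.na(wc3$r["a", "c"]))
})
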