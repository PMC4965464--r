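# Report assembly and CLI entry points.

local_report_config <- function(studies, ...) {
  analysis_config(input = studies, out_dir = withr::local_tempdir(
    .local_envir = parent.frame()), ...)
}

test_that("run_summary emits forest and heterogeneity tables for synthetic input", {
  lit <- generate_literature(simulation_config(n_studies = 120, seed = 301))
  cfg <- local_report_config(lit$studies, outcomes = "CER")
  res <- suppressMessages(run_summary(cfg))
  expect_named(res, "CER")
  expect_true(file.exists(file.path(cfg$out_dir, "forest.csv")))
  expect_true(file.exists(file.path(cfg$out_dir,
                                    "summary_heterogeneity.csv")))
  forest <- utils::read.csv(file.path(cfg$out_dir, "forest.csv"))
  expect_true("overall" %in% forest$moderator)
  # stress and chronology subgroup rows are present
  expect_true(all(c("stress", "chronology") %in% forest$moderator))
  het <- utils::read.csv(file.path(cfg$out_dir, "summary_heterogeneity.csv"))
  expect_equal(het$df[het$moderator == "stress"], 1L)
  expect_equal(het$df[het$moderator == "chronology"], 6L)
})

test_that("run_summary handles degenerate inputs", {
  tab <- make_study_table(2.0, 1.0)
  cfg <- local_report_config(tab, outcomes = "CER", subgroup = character(0))
  res <- suppressMessages(run_summary(cfg))
  expect_equal(res$CER$pooled$mu_hat, log(2))
  expect_equal(res$CER$pooled$k, 1L)
  # requesting an outcome with no studies errors
  cfg2 <- local_report_config(tab, outcomes = c("CER", "GS"))
  expect_error(suppressMessages(run_summary(cfg2)), "GS")
})

test_that("run_regression reports slopes, skips unusable moderators, writes all tables", {
  lit <- generate_literature(simulation_config(
    n_studies = 150, seed = 302,
    moderator_slopes = c(colonization_pct = 0.004)))
  st <- lit$studies
  st$leaf_p_es <- NA_real_   # entirely missing moderator must be skipped
  cfg <- local_report_config(st, outcomes = "CER")
  w <- testthat::capture_warnings(
    res <- suppressMessages(run_regression(cfg)))
  expect_true(any(grepl("leaf_p_es", w)))
  # complete-case multi-factor subset is empty too, so that is skipped
  expect_true(any(grepl("multi-factor", w)))
  expect_false("leaf_p_es" %in% names(res$CER$single))
  expect_true("colonization_pct" %in% names(res$CER$single))
  single <- utils::read.csv(file.path(cfg$out_dir, "regression_single.csv"))
  expect_true(all(c("intercept", "slope", "average_slope", "p", "i2",
                    "p_hetero", "r2_analog") %in% names(single)))
  expect_true(file.exists(file.path(cfg$out_dir,
                                    "scatter_CER_colonization_pct.csv")))
  expect_true(file.exists(file.path(cfg$out_dir,
                                    "moderator_correlation_CER.csv")))
})

test_that("noiseless linear synthetic data reproduces the generating slope", {
  x <- seq(5, 95, length.out = 30)
  tab <- do.call(rbind, lapply(seq_along(x), function(i)
    make_study_table(exp(0.1 + 0.004 * x[i]), 1.0,
                     study_id = sprintf("p%02d", i),
                     colonization_pct = x[i])))
  cfg <- local_report_config(tab, outcomes = "CER",
                             moderators = "colonization_pct")
  res <- suppressMessages(suppressWarnings(run_regression(cfg)))
  fit <- res$CER$single$colonization_pct
  expect_equal(fit$coef$estimate[2], 0.004, tolerance = 1e-6)
  expect_equal(fit$coef$estimate[1], 0.1, tolerance = 1e-6)
})

test_that("run_diagnostics names the planted extreme and respects k thresholds", {
  lit <- generate_literature(simulation_config(n_studies = 60, seed = 303))
  st <- lit$studies
  # plant an extreme study: huge AM/NM ratio
  st$am_mean[st$study_id == "S0001"] <- 1000
  st$nm_mean[st$study_id == "S0001"] <- 1
  cfg <- local_report_config(st, outcomes = "CER")
  res <- suppressMessages(run_diagnostics(cfg))
  expect_equal(attr(res$CER$loo, "most_influential_study"), "S0001")
  expect_true(file.exists(file.path(cfg$out_dir, "funnel_CER.csv")))
  expect_true(file.exists(file.path(cfg$out_dir, "leave_one_out_CER.csv")))
  expect_true(file.exists(file.path(cfg$out_dir, "bias_tests.csv")))
  # k = 2: leave-one-out runs, Begg-Mazumdar skipped with a warning
  two <- rbind(make_study_table(2, 1, study_id = "a"),
               make_study_table(3, 1, study_id = "b"))
  cfg2 <- local_report_config(two, outcomes = "CER")
  expect_warning(res2 <- suppressMessages(run_diagnostics(cfg2)),
                 "k < 3")
  expect_null(res2$CER$begg)
  expect_equal(nrow(res2$CER$loo), 2L)
})

test_that("identical config and input reproduce byte-identical reports", {
  lit <- generate_literature(simulation_config(n_studies = 50, seed = 304))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  for (d in c(d1, d2)) {
    cfg <- analysis_config(input = lit$studies, outcomes = "CER",
                           out_dir = d)
    suppressMessages(run_summary(cfg))
  }
  f1 <- readLines(file.path(d1, "forest.csv"))
  f2 <- readLines(file.path(d2, "forest.csv"))
  expect_identical(f1, f2)
})

test_that("the CLI runs simulate and summarize end to end", {
  d <- withr::local_tempdir()
  status <- mycometa_cli(c("simulate", "--n-studies", "40", "--seed", "7",
                           "--out", d))
  expect_equal(status, 0L)
  expect_true(file.exists(file.path(d, "synthetic_studies.csv")))
  status2 <- suppressMessages(mycometa_cli(
    c("summarize", "--input", file.path(d, "synthetic_studies.csv"),
      "--outcome", "CER", "--out", d)))
  expect_equal(status2, 0L)
  expect_true(file.exists(file.path(d, "forest.csv")))
  # malformed invocation exits nonzero
  expect_equal(suppressMessages(mycometa_cli(c("summarize"))), 1L)
  expect_equal(suppressMessages(mycometa_cli(c("nonsense"))), 1L)
})
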