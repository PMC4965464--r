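# Report assembly and command-line entry points tying the stages into the
# standard analysis sequence: summary effects and subgroups, single- and
# multi-factor meta-regression, and bias/sensitivity diagnostics. Every
# figure-shaped output is backed by a CSV so nothing depends on graphics.

#' Analysis configuration
#'
#' @param input Path to a study-table CSV, or a study-table data frame.
#' @param outcomes Outcomes to analyze (subset of CER, GS, E).
#' @param r Time-point correlation constant (default 0.1).
#' @param floor_fraction Zero-adjustment floor fraction (default 0.01).
#' @param moderators Quantitative moderators for regression (defaults to
#'   the five physiological moderators plus publication year).
#' @param subgroup Categorical moderator for subgroup analysis
#'   (`"stress"`, `"chronology"`, or both).
#' @param range_policy Moderator range for the raw average slope:
#'   `"data"` (observed min/max) or a named list of `c(min, max)` bounds.
#' @param out_dir Output directory for report CSVs.
#' @param seed Seed recorded for reproducibility of any randomized step.
#' @return List of class `"analysis_config"`.
#' @export
analysis_config <- function(input, outcomes = c("CER", "GS", "E"), r = 0.1,
                            floor_fraction = 0.01,
                            moderators = .ALL_MODERATORS,
                            subgroup = c("stress", "chronology"),
                            range_policy = "data",
                            out_dir = ".", seed = 1L) {
  outcomes <- toupper(outcomes)
  if (!length(outcomes) || !all(outcomes %in% .OUTCOMES))
    stop("outcomes must be a non-empty subset of CER, GS, E", call. = FALSE)
  if (!all(moderators %in% .ALL_MODERATORS))
    stop("unknown moderators: ",
         paste(setdiff(moderators, .ALL_MODERATORS), collapse = ", "),
         call. = FALSE)
  structure(list(input = input, outcomes = outcomes, r = r,
                 floor_fraction = floor_fraction, moderators = moderators,
                 subgroup = subgroup, range_policy = range_policy,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "analysis_config")
}

.load_effects <- function(config) {
  studies <- if (is.character(config$input)) read_study_table(config$input)
             else as_study_table(as.data.frame(config$input))
  effect_table(studies, r = config$r, floor_fraction = config$floor_fraction)
}

.ensure_dir <- function(d) {
  if (!dir.exists(d)) dir.create(d, recursive = TRUE)
  d
}

.write_report <- function(df, config, name) {
  path <- file.path(.ensure_dir(config$out_dir), name)
  utils::write.csv(df, path, row.names = FALSE)
  path
}

.rbind_rows <- function(rows) {
  if (!length(rows)) return(NULL)
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

.moderator_range <- function(config, moderator, x) {
  rp <- config$range_policy
  if (is.list(rp) && !is.null(rp[[moderator]]))
    return(rp[[moderator]])
  range(x)
}

#' Summary-effect analysis per outcome with subgroups
#'
#' For each selected outcome: REML random-effects pooled effect with CI,
#' percent change and heterogeneity, plus stress and chronology subgroup
#' analyses. Writes a heterogeneity table CSV
#' (`summary_heterogeneity.csv`), a forest-data CSV (`forest.csv`), and
#' logs k, exclusions, and imputation counts.
#'
#' @param config An [analysis_config()].
#' @return Invisible list per outcome: `pooled`, `heterogeneity`,
#'   `subgroups`.
#' @export
run_summary <- function(config) {
  es_all <- .load_effects(config)
  results <- list()
  het_rows <- forest_rows <- list()
  for (oc in config$outcomes) {
    es <- es_all[es_all$outcome == oc, , drop = FALSE]
    if (nrow(es) == 0L)
      stop("no usable studies for outcome ", oc, call. = FALSE)
    pooled <- pool_effects(es)
    het <- if (nrow(es) >= 2L) heterogeneity(es) else NULL
    message(sprintf("[%s] k = %d, imputed n for %d studies, floored %d",
                    oc, nrow(es), attr(es_all, "n_imputed"),
                    attr(es_all, "n_floored")))
    forest_rows[[paste0(oc, ".all")]] <- data.frame(
      outcome = oc, moderator = "overall", level = "all", k = pooled$k,
      mu_hat = pooled$mu_hat, ci_low = pooled$ci_low,
      ci_high = pooled$ci_high, ratio = pooled$ratio,
      percent_change = round(pooled$percent_change, 1),
      p_value = pooled$p_value, stringsAsFactors = FALSE)
    subs <- list()
    for (sg in config$subgroup) {
      labels <- switch(sg,
                       stress = es$stress,
                       chronology = as.character(chronology_bin(es$year)),
                       stop("unknown subgroup moderator: ", sg, call. = FALSE))
      ok <- !is.na(labels)
      if (length(unique(labels[ok])) < 2L) next
      sr <- subgroup_analysis(es[ok, , drop = FALSE], labels[ok])
      subs[[sg]] <- sr
      het_rows[[paste0(oc, ".", sg)]] <- data.frame(
        outcome = oc, moderator = sg, q_between = round(sr$q_between, 1),
        n = sr$k, df = sr$df_between, i2 = round(sr$i2, 1),
        p_hetero = sr$p_hetero, p_between = sr$p_between,
        stringsAsFactors = FALSE)
      lv <- sr$levels
      forest_rows[[paste0(oc, ".", sg)]] <- data.frame(
        outcome = oc, moderator = sg, level = lv$level, k = lv$k,
        mu_hat = lv$mu_hat, ci_low = lv$ci_low, ci_high = lv$ci_high,
        ratio = lv$ratio, percent_change = round(lv$percent_change, 1),
        p_value = lv$p_value, stringsAsFactors = FALSE)
    }
    results[[oc]] <- list(pooled = pooled, heterogeneity = het,
                          subgroups = subs)
  }
  het_df <- .rbind_rows(het_rows)
  if (!is.null(het_df))
    .write_report(het_df, config, "summary_heterogeneity.csv")
  .write_report(.rbind_rows(forest_rows), config, "forest.csv")
  invisible(results)
}

#' Single- and multi-factor meta-regression per outcome
#'
#' Fits every configured moderator singly (listwise deletion per
#' moderator), assembles the regression table (intercept, slope, raw
#' average slope over the moderator range, Knapp-Hartung p, residual I^2,
#' p_hetero, R^2 analog), the weighted moderator correlation matrix, and
#' the incremental (test-of-change) table on the complete-case subset
#' with all five physiological moderators. Writes
#' `regression_single.csv`, `moderator_correlation.csv`,
#' `regression_multi.csv`, and per-moderator scatter CSVs.
#'
#' @param config An [analysis_config()].
#' @return Invisible list per outcome with elements `single`, `multi`,
#'   `correlation`.
#' @export
run_regression <- function(config) {
  es_all <- .load_effects(config)
  results <- list()
  single_rows <- multi_rows <- list()
  for (oc in config$outcomes) {
    es <- es_all[es_all$outcome == oc, , drop = FALSE]
    if (nrow(es) == 0L)
      stop("no usable studies for outcome ", oc, call. = FALSE)
    fits <- list()
    for (mod in config$moderators) {
      x <- es[[mod]]
      ok <- !is.na(x)
      if (sum(ok) < 4L) {
        warning("moderator ", mod, " skipped for ", oc,
                ": fewer than 4 complete cases", call. = FALSE)
        next
      }
      sub <- es[ok, , drop = FALSE]
      fit <- fit_meta_regression(sub, stats::setNames(
        data.frame(x[ok]), mod))
      rng <- .moderator_range(config, mod, x[ok])
      slope_row <- fit$coef[fit$coef$term == mod, ]
      int_row <- fit$coef[fit$coef$term == "intercept", ]
      avg <- average_raw_slope(int_row$estimate, slope_row$estimate,
                               rng[1], rng[2])
      fits[[mod]] <- fit
      single_rows[[paste0(oc, ".", mod)]] <- data.frame(
        outcome = oc, moderator = mod, n = fit$k,
        intercept = round(int_row$estimate, 4),
        slope = round(slope_row$estimate, 4),
        average_slope = round(avg, 4), p = slope_row$p,
        i2 = round(fit$i2, 1), p_hetero = fit$p_hetero,
        r2_analog = if (is.na(fit$r2_analog)) NA else
          round(fit$r2_analog, 1),
        stringsAsFactors = FALSE)
      pred <- as.numeric(fit$X %*% fit$coef$estimate)
      scatter <- data.frame(study_id = fit$study_id, x = x[ok],
                            lnr = fit$y, weight = fit$w, prediction = pred,
                            stringsAsFactors = FALSE)
      .write_report(scatter, config,
                    sprintf("scatter_%s_%s.csv", oc, mod))
    }
    # weighted correlations among the physiological moderators, weights
    # from the intercept-only random-effects model of this outcome
    tau2_0 <- if (nrow(es) >= 2L) estimate_tau2(es) else 0
    corr <- weighted_moderator_correlation(es[, .MODERATORS, drop = FALSE],
                                           1 / (es$variance + tau2_0))
    # incremental tests on the complete-case subset of the five
    # physiological moderators
    cc <- stats::complete.cases(es[, .MODERATORS, drop = FALSE])
    multi <- NULL
    if (sum(cc) >= length(.MODERATORS) + 3L) {
      sub <- es[cc, , drop = FALSE]
      multi <- lapply(.MODERATORS, function(mod)
        incremental_moderator_test(sub, sub[, .MODERATORS, drop = FALSE],
                                   mod))
      names(multi) <- .MODERATORS
      multi_rows[[oc]] <- data.frame(
        outcome = oc, moderator = .MODERATORS, n = sum(cc),
        p_test = vapply(multi, function(m) m$p_test, numeric(1)),
        stringsAsFactors = FALSE)
    } else {
      warning("multi-factor regression skipped for ", oc,
              ": insufficient complete cases", call. = FALSE)
    }
    results[[oc]] <- list(single = fits, multi = multi, correlation = corr)
    cor_df <- as.data.frame(corr$r)
    cor_df <- cbind(moderator = rownames(corr$r), cor_df)
    .write_report(cor_df, config,
                  sprintf("moderator_correlation_%s.csv", oc))
  }
  single_df <- .rbind_rows(single_rows)
  if (!is.null(single_df))
    .write_report(single_df, config, "regression_single.csv")
  multi_df <- .rbind_rows(multi_rows)
  if (!is.null(multi_df))
    .write_report(multi_df, config, "regression_multi.csv")
  invisible(results)
}

#' Publication-bias and sensitivity diagnostics per outcome
#'
#' Runs the Begg-Mazumdar rank-correlation test (skipped with a warning
#' when k < 3), writes funnel-point CSVs, and the leave-one-out
#' sensitivity trace with the most influential study named. Writes
#' `bias_tests.csv`, `funnel_<outcome>.csv`, `leave_one_out_<outcome>.csv`.
#'
#' @param config An [analysis_config()].
#' @return Invisible list per outcome: `begg`, `funnel`, `loo`.
#' @export
run_diagnostics <- function(config) {
  es_all <- .load_effects(config)
  results <- list()
  bias_rows <- list()
  for (oc in config$outcomes) {
    es <- es_all[es_all$outcome == oc, , drop = FALSE]
    if (nrow(es) == 0L)
      stop("no usable studies for outcome ", oc, call. = FALSE)
    begg <- NULL
    if (nrow(es) >= 3L) {
      begg <- begg_mazumdar(es)
      bias_rows[[oc]] <- data.frame(outcome = oc, kendall_tau = begg$tau,
                                    p = begg$p, k = begg$k,
                                    stringsAsFactors = FALSE)
    } else {
      warning("Begg-Mazumdar skipped for ", oc, ": k < 3", call. = FALSE)
    }
    fun <- funnel_data(es)
    .write_report(fun, config, sprintf("funnel_%s.csv", oc))
    loo <- NULL
    if (nrow(es) >= 2L) {
      loo <- leave_one_out(es)
      loo_out <- as.data.frame(loo)
      loo_out$pct_change_from_full <- round(loo_out$pct_change_from_full, 2)
      .write_report(loo_out, config, sprintf("leave_one_out_%s.csv", oc))
      message(sprintf("[%s] most influential study: %s (max ratio change %.4f)",
                      oc, attr(loo, "most_influential_study"),
                      attr(loo, "max_abs_change")))
    }
    results[[oc]] <- list(begg = begg, funnel = fun, loo = loo)
  }
  bias_df <- .rbind_rows(bias_rows)
  if (!is.null(bias_df))
    .write_report(bias_df, config, "bias_tests.csv")
  invisible(results)
}

#' Command-line interface
#'
#' Subcommands: `summarize`, `regress`, `diagnose`, `simulate`, `recover`.
#' Flags: `--input`, `--outcome` (comma-separated), `--r`, `--floor`,
#' `--moderators` (comma-separated), `--subgroup`, `--range-policy`,
#' `--out`, `--seed`, and for the generator `--n-studies`, `--mu`,
#' `--tau2`, `--replicates`.
#'
#' @param args Character vector of command-line arguments (defaults to
#'   the process arguments).
#' @return Integer exit status, invisibly.
#' @export
mycometa_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    message("usage: mycometa <summarize|regress|diagnose|simulate|recover> [options]")
    return(invisible(1L))
  }
  cmd <- args[1]
  opts <- list(
    optparse::make_option("--input", type = "character", default = NULL),
    optparse::make_option("--outcome", type = "character",
                          default = "CER,GS,E"),
    optparse::make_option("--r", type = "double", default = 0.1),
    optparse::make_option("--floor", type = "double", default = 0.01),
    optparse::make_option("--moderators", type = "character",
                          default = paste(.ALL_MODERATORS, collapse = ",")),
    optparse::make_option("--subgroup", type = "character",
                          default = "stress,chronology"),
    optparse::make_option("--range-policy", type = "character",
                          default = "data", dest = "range_policy"),
    optparse::make_option("--out", type = "character", default = "."),
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option("--n-studies", type = "integer", default = 583L,
                          dest = "n_studies"),
    optparse::make_option("--mu", type = "double", default = 0.399),
    optparse::make_option("--tau2", type = "double", default = 0.05),
    optparse::make_option("--replicates", type = "integer", default = 10L))
  parsed <- optparse::parse_args(optparse::OptionParser(option_list = opts),
                                 args = args[-1])
  status <- tryCatch({
    if (cmd %in% c("summarize", "regress", "diagnose")) {
      if (is.null(parsed$input)) stop("--input is required", call. = FALSE)
      cfg <- analysis_config(
        input = parsed$input,
        outcomes = strsplit(parsed$outcome, ",")[[1]],
        r = parsed$r, floor_fraction = parsed$floor,
        moderators = strsplit(parsed$moderators, ",")[[1]],
        subgroup = strsplit(parsed$subgroup, ",")[[1]],
        range_policy = parsed$range_policy,
        out_dir = parsed$out, seed = parsed$seed)
      switch(cmd,
             summarize = run_summary(cfg),
             regress = run_regression(cfg),
             diagnose = run_diagnostics(cfg))
    } else if (cmd == "simulate") {
      cfg <- simulation_config(n_studies = parsed$n_studies, mu = parsed$mu,
                               tau2 = parsed$tau2, seed = parsed$seed)
      lit <- generate_literature(cfg)
      .ensure_dir(parsed$out)
      utils::write.csv(as.data.frame(lit$studies),
                       file.path(parsed$out, "synthetic_studies.csv"),
                       row.names = FALSE)
      utils::write.csv(lit$truth,
                       file.path(parsed$out, "synthetic_truth.csv"),
                       row.names = FALSE)
    } else if (cmd == "recover") {
      cfg <- simulation_config(n_studies = parsed$n_studies, mu = parsed$mu,
                               tau2 = parsed$tau2, seed = parsed$seed)
      rec <- recovery_experiment(cfg, parsed$replicates)
      .ensure_dir(parsed$out)
      utils::write.csv(as.data.frame(rec),
                       file.path(parsed$out, "recovery.csv"),
                       row.names = FALSE)
      print(rec)
    } else {
      stop("unknown subcommand: ", cmd, call. = FALSE)
    }
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
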