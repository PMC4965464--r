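# Synthetic-literature generator. Emulates the statistical structure of a
# paired AM-vs-NM gas-exchange study table: true effects Normal(mu, tau2)
# on the lnR scale with moderator-linked slopes and a stress shift,
# non-parametric within-study variances implied by small sample sizes,
# exchangeably correlated time-points, occasional zero/negative readings,
# and missing sample sizes. Every pipeline stage is then testable by
# parameter recovery without any external data.

.default_moderator_distributions <- function() {
  list(
    colonization_pct = list(type = "uniform", min = 5, max = 95),
    shoot_dw_es      = list(type = "lognormal", meanlog = log(1.3), sdlog = 0.4),
    leaf_p_es        = list(type = "lognormal", meanlog = log(1.3), sdlog = 0.4),
    nm_leaf_np       = list(type = "uniform", min = 5, max = 30),
    leaf_np_es       = list(type = "lognormal", meanlog = log(0.9), sdlog = 0.25),
    year             = list(type = "uniform_int", min = 1980, max = 2014)
  )
}

.draw_moderator <- function(spec, n) {
  switch(spec$type,
         uniform = stats::runif(n, spec$min, spec$max),
         uniform_int = sample(seq(spec$min, spec$max), n, replace = TRUE),
         lognormal = stats::rlnorm(n, spec$meanlog, spec$sdlog),
         normal = stats::rnorm(n, spec$mean, spec$sd),
         stop("unknown moderator distribution type: ", spec$type,
              call. = FALSE))
}

#' Configuration of a synthetic literature
#'
#' Bundles and validates all generator parameters. True per-study effects
#' on the lnR scale are
#' `theta_i = mu + sum_j slope_j (X_ij - mean(X_j)) +
#' stress_shift (S_i - stress_fraction) + Normal(0, tau2)`,
#' so `mu` remains the grand mean whatever the slopes. Observed
#' per-time-point lnR values are `theta_i` plus exchangeably correlated
#' within-study noise whose variance equals the non-parametric variance
#' of the study's true sample sizes, making the sample-size weighting of
#' the analysis exactly correct for the generated data.
#'
#' @param n_studies Number of studies.
#' @param mu Grand mean lnR (default 0.399, a 49% stimulation).
#' @param tau2 Between-study variance of true effects.
#' @param moderator_slopes Named numeric vector of lnR-scale slopes; names
#'   must be moderator columns or `"year"`. Defaults to all 0.
#' @param moderator_distributions Named list of distribution specs
#'   (`type` plus parameters); see defaults in the source.
#' @param stress_fraction Share of studies under environmental stress.
#' @param stress_shift Additive lnR shift of stressed studies (default
#'   `log(1.72/1.39)`, echoing the observed stressed-vs-unstressed
#'   contrast in carbon exchange rate).
#' @param sample_sizes Integer pool the per-treatment sample sizes are
#'   drawn from (uniformly).
#' @param missing_n_fraction Share of studies whose sample sizes are
#'   hidden from the analyst (they then fall under the n = 1 / n = 2
#'   imputation rules).
#' @param timepoint_probs Named numeric vector: probability of each
#'   time-point count (names are the counts).
#' @param r_true Exchangeable correlation among time-point errors.
#' @param zero_value_rate Probability per study that one reported value is
#'   replaced by a zero or small negative reading (exercising the floor
#'   adjustment).
#' @param nm_mean_scale Median NM outcome mean, in outcome units.
#' @param nm_mean_sdlog Log-scale spread of NM means.
#' @param within_noise Set `FALSE` to switch off within-study noise (for
#'   degenerate-limit tests).
#' @param outcome Outcome label written to the table (CER, GS or E).
#' @param seed Integer root seed; same config + seed reproduces the table
#'   bit for bit.
#' @return Validated list of class `"simulation_config"`.
#' @export
simulation_config <- function(n_studies = 583L, mu = 0.399, tau2 = 0.05,
                              moderator_slopes = NULL,
                              moderator_distributions = NULL,
                              stress_fraction = 0.3,
                              stress_shift = log(1.72 / 1.39),
                              sample_sizes = 3:8,
                              missing_n_fraction = 0.04,
                              timepoint_probs = c("1" = 0.75, "2" = 0.10,
                                                  "3" = 0.06, "4" = 0.05,
                                                  "5" = 0.04),
                              r_true = 0.1, zero_value_rate = 0.003,
                              nm_mean_scale = 10, nm_mean_sdlog = 0.6,
                              within_noise = TRUE,
                              outcome = "CER", seed = 1L) {
  dists <- .default_moderator_distributions()
  if (!is.null(moderator_distributions))
    dists[names(moderator_distributions)] <- moderator_distributions
  slopes <- stats::setNames(numeric(length(dists)), names(dists))
  if (!is.null(moderator_slopes)) {
    unknown <- setdiff(names(moderator_slopes), names(slopes))
    if (length(unknown))
      stop("unknown moderators in slopes: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    slopes[names(moderator_slopes)] <- moderator_slopes
  }
  cfg <- list(n_studies = as.integer(n_studies), mu = mu, tau2 = tau2,
              moderator_slopes = slopes, moderator_distributions = dists,
              stress_fraction = stress_fraction, stress_shift = stress_shift,
              sample_sizes = as.integer(sample_sizes),
              missing_n_fraction = missing_n_fraction,
              timepoint_probs = timepoint_probs, r_true = r_true,
              zero_value_rate = zero_value_rate,
              nm_mean_scale = nm_mean_scale, nm_mean_sdlog = nm_mean_sdlog,
              within_noise = isTRUE(within_noise),
              outcome = outcome, seed = as.integer(seed))
  problems <- character(0)
  for (f in c("stress_fraction", "missing_n_fraction", "r_true",
              "zero_value_rate"))
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0 || cfg[[f]] > 1)
      problems <- c(problems, paste0(f, " must lie in [0, 1]"))
  if (cfg$tau2 < 0) problems <- c(problems, "tau2 must be >= 0")
  if (cfg$n_studies < 1) problems <- c(problems, "n_studies must be >= 1")
  if (any(cfg$sample_sizes < 1))
    problems <- c(problems, "sample_sizes must be >= 1")
  if (abs(sum(cfg$timepoint_probs) - 1) > 1e-8)
    problems <- c(problems, "timepoint_probs must sum to 1")
  if (cfg$nm_mean_scale <= 0)
    problems <- c(problems, "nm_mean_scale must be positive")
  if (!cfg$outcome %in% .OUTCOMES)
    problems <- c(problems, "outcome must be CER, GS or E")
  if (length(problems))
    stop("invalid simulation config: ", paste(problems, collapse = "; "),
         call. = FALSE)
  class(cfg) <- "simulation_config"
  cfg
}

#' Generate a synthetic study table
#'
#' Draws a full literature under a [simulation_config()]: moderators,
#' stress assignment, true effects, sample sizes, correlated time-point
#' readings, injected zero/negative values, and hidden sample sizes. All
#' randomness flows from the single root seed in the config.
#'
#' @param config A [simulation_config()].
#' @return List with `studies` (a study table in the [read_study_table()]
#'   dialect), `truth` (one row per study: true `theta`, true sample
#'   sizes, moderators), and `config`.
#' @export
generate_literature <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  k <- config$n_studies
  dists <- config$moderator_distributions
  M <- as.data.frame(lapply(dists, .draw_moderator, n = k))
  stressed <- stats::runif(k) < config$stress_fraction
  slopes <- config$moderator_slopes
  lin <- rep(config$mu, k)
  for (nm in names(slopes))
    if (slopes[[nm]] != 0)
      lin <- lin + slopes[[nm]] * (M[[nm]] - mean(M[[nm]]))
  lin <- lin + config$stress_shift * (stressed - config$stress_fraction)
  theta <- lin + stats::rnorm(k, 0, sqrt(config$tau2))
  m_counts <- as.integer(sample(names(config$timepoint_probs), k,
                                replace = TRUE,
                                prob = config$timepoint_probs))
  # equal AM/NM sample sizes within multi-time-point studies; independent
  # draws for single-time-point studies
  n_am <- sample(config$sample_sizes, k, replace = TRUE)
  n_nm <- ifelse(m_counts > 1L, n_am,
                 sample(config$sample_sizes, k, replace = TRUE))
  hide_n <- stats::runif(k) < config$missing_n_fraction
  disp <- ifelse(hide_n,
                 ifelse(stats::runif(k) < 0.6, "lsd_or_se", "none"),
                 "none")
  inject <- stats::runif(k) < config$zero_value_rate
  rows <- vector("list", k)
  for (i in seq_len(k)) {
    m <- m_counts[i]
    v1 <- nonparametric_variance(n_am[i], n_nm[i])
    if (config$within_noise) {
      # exchangeable errors: corr r_true, variance v1
      z0 <- stats::rnorm(1)
      eps <- sqrt(v1) * (sqrt(config$r_true) * z0 +
                           sqrt(1 - config$r_true) * stats::rnorm(m))
    } else {
      eps <- numeric(m)
    }
    nm_means <- config$nm_mean_scale *
      exp(stats::rnorm(m, 0, config$nm_mean_sdlog))
    am_means <- nm_means * exp(theta[i] + eps)
    if (inject[i]) {
      slot <- sample.int(2L * m, 1L)
      val0 <- if (stats::runif(1) < 0.5) 0 else
        -0.02 * c(am_means, nm_means)[slot]
      if (slot <= m) am_means[slot] <- val0 else nm_means[slot - m] <- val0
    }
    rows[[i]] <- data.frame(
      study_id = sprintf("S%04d", i), article_id = sprintf("A%04d", i),
      outcome = config$outcome, timepoint_label = paste0("t", seq_len(m)),
      am_mean = am_means, nm_mean = nm_means,
      n_am = if (hide_n[i]) NA_integer_ else n_am[i],
      n_nm = if (hide_n[i]) NA_integer_ else n_nm[i],
      dispersion_reported = disp[i],
      colonization_pct = M$colonization_pct[i],
      shoot_dw_es = M$shoot_dw_es[i], leaf_p_es = M$leaf_p_es[i],
      nm_leaf_np = M$nm_leaf_np[i], leaf_np_es = M$leaf_np_es[i],
      stress = if (stressed[i]) "stressed" else "unstressed",
      year = as.integer(M$year[i]), stringsAsFactors = FALSE)
  }
  studies <- as_study_table(do.call(rbind, rows))
  truth <- data.frame(study_id = sprintf("S%04d", seq_len(k)), theta = theta,
                      stressed = stressed, m = m_counts,
                      n_am_true = n_am, n_nm_true = n_nm,
                      n_hidden = hide_n, zero_injected = inject,
                      M, stringsAsFactors = FALSE)
  list(studies = studies, truth = truth, config = config)
}

#' Parameter-recovery experiment
#'
#' Repeatedly generates a literature, runs the full pipeline (study table
#' to effect sizes to REML pooling, plus a meta-regression on every
#' moderator with a nonzero generating slope), and compares estimates to
#' the generating values. Replicate seeds are derived from the config
#' seed.
#'
#' @param config A [simulation_config()].
#' @param replicates Number of replicates (>= 2).
#' @return Data frame of class `"recovery_summary"`, one row per
#'   parameter: truth, mean estimate, `bias`, `mc_se` (Monte-Carlo
#'   standard error of the bias), `rmse`, and 95% CI `coverage` (`NA`
#'   where no interval is produced). Failed replicates are recorded in
#'   attribute `failures`, not fatal.
#' @export
recovery_experiment <- function(config, replicates) {
  stopifnot(inherits(config, "simulation_config"), replicates >= 2)
  slopes <- config$moderator_slopes[config$moderator_slopes != 0]
  est <- list()
  failures <- list()
  for (rep_i in seq_len(replicates)) {
    cfg_i <- config
    cfg_i$seed <- config$seed + rep_i
    res <- tryCatch({
      lit <- generate_literature(cfg_i)
      es <- suppressWarnings(effect_table(lit$studies, r = config$r_true))
      tau2 <- estimate_tau2(es)
      pooled <- pool_effects(es, tau2 = tau2)
      row <- list(mu = pooled$mu_hat, tau2 = tau2,
                  mu_cover = pooled$ci_low <= config$mu &
                    config$mu <= pooled$ci_high)
      for (nm in names(slopes)) {
        fit <- fit_meta_regression(es, es[, nm, drop = FALSE])
        cr <- fit$coef[fit$coef$term == nm, ]
        row[[paste0("slope_", nm)]] <- cr$estimate
        row[[paste0("cover_", nm)]] <- cr$ci_low <= slopes[[nm]] &
          slopes[[nm]] <= cr$ci_high
      }
      row
    }, error = function(e) e)
    if (inherits(res, "error")) failures[[length(failures) + 1L]] <-
        list(replicate = rep_i, message = conditionMessage(res))
    else est[[length(est) + 1L]] <- res
  }
  if (!length(est)) stop("all replicates failed", call. = FALSE)
  getcol <- function(nm) vapply(est, function(e) as.numeric(e[[nm]]),
                                numeric(1))
  summarize <- function(name, truth, values, coverage = NULL) {
    data.frame(parameter = name, truth = truth, mean_estimate = mean(values),
               bias = mean(values) - truth,
               mc_se = stats::sd(values) / sqrt(length(values)),
               rmse = sqrt(mean((values - truth)^2)),
               coverage = if (is.null(coverage)) NA_real_ else mean(coverage),
               stringsAsFactors = FALSE)
  }
  out <- rbind(
    summarize("mu", config$mu, getcol("mu"), getcol("mu_cover") > 0.5),
    summarize("tau2", config$tau2, getcol("tau2")))
  for (nm in names(slopes))
    out <- rbind(out, summarize(paste0("slope_", nm), slopes[[nm]],
                                getcol(paste0("slope_", nm)),
                                getcol(paste0("cover_", nm)) > 0.5))
  attr(out, "replicates") <- length(est)
  attr(out, "failures") <- failures
  class(out) <- c("recovery_summary", "data.frame")
  out
}
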