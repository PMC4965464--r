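# Independent oracles and fixture builders shared across test files.

# Brute-force restricted-likelihood grid maximization for the
# intercept-only model; independent of the Fisher-scoring path.
oracle_reml_grid <- function(y, v, lower = 0, upper = NULL, step = 1e-5) {
  if (is.null(upper)) upper <- max(1, 4 * stats::var(y))
  grid <- seq(lower, upper, by = step)
  # vectorized over the grid in blocks to bound memory
  best_ll <- -Inf
  best_t2 <- lower
  block <- 20000L
  for (start in seq(1L, length(grid), by = block)) {
    g <- grid[seq(start, min(start + block - 1L, length(grid)))]
    vt <- outer(v, g, "+")          # k x block
    w <- 1 / vt
    sw <- colSums(w)
    mu <- colSums(w * y) / sw
    q <- colSums(w * (y - rep(mu, each = length(y)))^2)
    ll_g <- -0.5 * (colSums(log(vt)) + log(sw) + q)
    i <- which.max(ll_g)
    if (ll_g[i] > best_ll) {
      best_ll <- ll_g[i]
      best_t2 <- g[i]
    }
  }
  best_t2
}

# Plain weighted least squares via lm(), as the reference fit.
oracle_wls <- function(y, X, w) {
  stats::coef(stats::lm(y ~ X - 1, weights = w))
}

# Random small meta-analytic instance for estimator cross-checks.
random_instance <- function(k, tau2 = 0.05, mu = 0.4) {
  v <- stats::runif(k, 0.1, 0.8)
  y <- stats::rnorm(k, mu, sqrt(tau2 + v))
  data.frame(lnr = y, variance = v)
}

# Minimal single-outcome study table, one row per time-point.
make_study_table <- function(am, nm, n_am = 4, n_nm = 4, outcome = "CER",
                             study_id = "s1", year = 2000,
                             stress = "unstressed", ...) {
  stopifnot(length(am) == length(nm))
  mods <- list(...)
  df <- data.frame(
    study_id = study_id, article_id = paste0("a_", study_id),
    outcome = outcome, timepoint_label = paste0("t", seq_along(am)),
    am_mean = am, nm_mean = nm, n_am = n_am, n_nm = n_nm,
    dispersion_reported = "none",
    colonization_pct = NA_real_, shoot_dw_es = NA_real_,
    leaf_p_es = NA_real_, nm_leaf_np = NA_real_, leaf_np_es = NA_real_,
    stress = stress, year = year, stringsAsFactors = FALSE)
  for (nm_i in names(mods)) df[[nm_i]] <- mods[[nm_i]]
  df
}

# Clean calibration config: true effects exactly Normal(mu, tau2), no
# stress shift, moderator slopes, zero injection, or hidden sample sizes.
clean_config <- function(n_studies, mu = 0.4, tau2 = 0.05, seed = 1L, ...) {
  simulation_config(n_studies = n_studies, mu = mu, tau2 = tau2,
                    stress_shift = 0, zero_value_rate = 0,
                    missing_n_fraction = 0, seed = seed, ...)
}
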