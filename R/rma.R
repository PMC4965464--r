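# Random-effects machinery: REML estimation of the between-study variance
# tau^2, inverse-variance pooling, heterogeneity statistics, and
# categorical (mixed-effects) subgroup analysis.

# Restricted log-likelihood of tau2 for y = X b + u + e, Var = v + tau2.
# Dropping constants: -0.5 * (sum log(v+t2) + log|X'WX| + sum w e^2).
.reml_ll <- function(tau2, y, v, X) {
  w <- 1 / (v + tau2)
  A <- crossprod(X, w * X)
  b <- solve(A, crossprod(X, w * y))
  e <- y - X %*% b
  -0.5 * (sum(log(v + tau2)) + determinant(A, logarithm = TRUE)$modulus[1] +
            sum(w * e^2))
}

# Fisher-scoring REML for tau2 with step-halving; O(k p^2) per iteration.
.reml_tau2 <- function(y, v, X = NULL, tol = 1e-10, maxit = 100L) {
  k <- length(y)
  if (is.null(X)) X <- matrix(1, k, 1)
  p <- ncol(X)
  if (k <= p) stop("need more studies than coefficients", call. = FALSE)
  # DerSimonian-Laird style start from the fixed-effect fit
  w0 <- 1 / v
  A0 <- crossprod(X, w0 * X)
  b0 <- solve(A0, crossprod(X, w0 * y))
  qe <- sum(w0 * (y - X %*% b0)^2)
  trp0 <- sum(w0) - sum(diag(solve(A0, crossprod(X, w0^2 * X))))
  tau2 <- max(0, (qe - (k - p)) / trp0)
  ll <- .reml_ll(tau2, y, v, X)
  conv <- FALSE
  for (it in seq_len(maxit)) {
    w <- 1 / (v + tau2)
    A <- crossprod(X, w * X)
    Ainv <- solve(A)
    B <- crossprod(X, w^2 * X)
    C <- crossprod(X, w^3 * X)
    b <- Ainv %*% crossprod(X, w * y)
    e <- as.numeric(y - X %*% b)
    trP <- sum(w) - sum(diag(Ainv %*% B))
    AB <- Ainv %*% B
    trPP <- sum(w^2) - 2 * sum(diag(Ainv %*% C)) + sum(diag(AB %*% AB))
    score <- 0.5 * (sum((w * e)^2) - trP)
    if (trPP <= 0) break
    step <- score / (0.5 * trPP)
    # step-halve until the restricted likelihood strictly improves (a
    # non-strict test lets the iteration ping-pong between equal-likelihood
    # points astride an interior maximum)
    repeat {
      cand <- max(0, tau2 + step)
      ll_cand <- .reml_ll(cand, y, v, X)
      if (ll_cand > ll || cand == tau2 || abs(step) < tol / 4) break
      step <- step / 2
    }
    delta <- abs(cand - tau2)
    tau2 <- cand
    ll <- ll_cand
    if (delta < tol) {
      conv <- TRUE
      break
    }
  }
  if (!conv && it == maxit) {
    cond <- simpleError(paste0("REML did not converge within ", maxit,
                               " iterations (last tau2 = ",
                               format(tau2), ")"))
    cond$tau2_last <- tau2
    class(cond) <- c("mycometa_no_convergence", class(cond))
    stop(cond)
  }
  list(tau2 = tau2, iterations = it, converged = TRUE)
}

.check_effects <- function(effects, min_k = 1L) {
  effects <- as.data.frame(effects)
  if (!all(c("lnr", "variance") %in% names(effects)))
    stop("'effects' needs columns lnr and variance", call. = FALSE)
  if (any(effects$variance <= 0)) stop("variances must be positive", call. = FALSE)
  if (nrow(effects) < min_k)
    stop("need at least ", min_k, " effect sizes", call. = FALSE)
  effects
}

#' REML estimate of the between-study variance
#'
#' Restricted maximum likelihood estimate of tau^2 in the intercept-only
#' random-effects model, via Fisher scoring with step-halving, truncated
#' at 0, converged when successive iterates differ by less than 1e-10
#' (cap 100 iterations).
#'
#' @param effects Data frame with columns `lnr` and `variance` (e.g., from
#'   [effect_table()]).
#' @return Non-negative tau^2 estimate.
#' @export
estimate_tau2 <- function(effects) {
  effects <- .check_effects(effects, min_k = 2L)
  .reml_tau2(effects$lnr, effects$variance)$tau2
}

#' Random-effects pooled summary effect
#'
#' Inverse-variance weighted mean with weights `1 / (variance + tau2)`,
#' normal-theory confidence interval and p-value, and the raw percent
#' change implied by the pooled lnR.
#'
#' @param effects Data frame with columns `lnr` and `variance`.
#' @param tau2 Between-study variance; estimated by REML when `NULL`
#'   (requires k >= 2; pass `tau2 = 0` explicitly for a single study).
#' @param level Confidence level (default 0.95).
#' @return Object of class `"summary_effect"`: a list with `mu_hat`, `se`,
#'   `ci_low`, `ci_high`, `p_value`, `k`, `tau2`, `ratio`,
#'   `percent_change`.
#' @export
pool_effects <- function(effects, tau2 = NULL, level = 0.95) {
  effects <- .check_effects(effects, min_k = 1L)
  if (is.null(tau2)) {
    tau2 <- if (nrow(effects) >= 2L) estimate_tau2(effects) else 0
  }
  w <- 1 / (effects$variance + tau2)
  mu <- sum(w * effects$lnr) / sum(w)
  se <- sqrt(1 / sum(w))
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- list(mu_hat = mu, se = se,
              ci_low = mu - z * se, ci_high = mu + z * se,
              p_value = 2 * stats::pnorm(-abs(mu / se)),
              k = nrow(effects), tau2 = tau2,
              ratio = exp(mu), percent_change = percent_change(mu))
  class(out) <- "summary_effect"
  out
}

#' @export
print.summary_effect <- function(x, ...) {
  cat(sprintf("Random-effects summary (k = %d)\n", x$k))
  cat(sprintf("  lnR = %.4f  [%.4f, %.4f],  ratio = %.2f (%+.0f%%),  p = %s\n",
              x$mu_hat, x$ci_low, x$ci_high, x$ratio, x$percent_change,
              format.pval(x$p_value, digits = 3)))
  cat(sprintf("  tau^2 = %.4f, se = %.4f\n", x$tau2, x$se))
  invisible(x)
}

#' Heterogeneity statistics
#'
#' Q is the sum of fixed-effect-weighted squared deviations about the
#' fixed-effect mean; I^2 = (Q - df) x 100 / Q truncated at 0 measures the
#' share of observed variation attributable to true between-study
#' heterogeneity; the p-value refers Q to a chi-square distribution with
#' k - 1 degrees of freedom. tau^2 is the REML estimate. Homogeneity is
#' conventionally considered untenable when `p_hetero < 0.1`.
#'
#' @param effects Data frame with columns `lnr` and `variance` (k >= 2).
#' @return List of class `"heterogeneity"`: `q_total`, `df`, `tau2`, `i2`
#'   (percent), `p_hetero`.
#' @export
heterogeneity <- function(effects) {
  effects <- .check_effects(effects, min_k = 2L)
  w <- 1 / effects$variance
  mu_f <- sum(w * effects$lnr) / sum(w)
  q <- sum(w * (effects$lnr - mu_f)^2)
  df <- nrow(effects) - 1L
  i2 <- if (q > 0) max(0, q - df) * 100 / q else 0
  out <- list(q_total = q, df = df, tau2 = estimate_tau2(effects), i2 = i2,
              p_hetero = stats::pchisq(q, df, lower.tail = FALSE))
  class(out) <- "heterogeneity"
  out
}

#' @export
print.heterogeneity <- function(x, ...) {
  cat(sprintf("Q = %.2f (df = %d, p = %s), I^2 = %.1f%%, tau^2 = %.4f\n",
              x$q_total, x$df, format.pval(x$p_hetero, digits = 3),
              x$i2, x$tau2))
  invisible(x)
}

#' Categorical subgroup (mixed-effects) analysis
#'
#' Estimates a single between-study variance common to all levels (REML on
#' the model with fixed level effects), pools each level with that common
#' tau^2, and tests the between-level heterogeneity Q_between of the level
#' means about the grand mean against a chi-square distribution with
#' (levels - 1) degrees of freedom. Residual (within-level) heterogeneity
#' is summarized by I^2 and its chi-square p-value.
#'
#' @param effects Data frame with columns `lnr` and `variance`.
#' @param labels Factor or character vector of level assignments, one per
#'   effect; at least 2 levels, each with at least 1 effect.
#' @param level Confidence level for per-level intervals.
#' @return Object of class `"subgroup_result"`: `q_between`, `df_between`,
#'   `p_between`, `common_tau2`, `i2`, `p_hetero`, `k`, and `levels`, a
#'   data frame of per-level summary effects.
#' @export
subgroup_analysis <- function(effects, labels, level = 0.95) {
  effects <- .check_effects(effects, min_k = 2L)
  labels <- factor(labels)
  if (length(labels) != nrow(effects))
    stop("'labels' must match 'effects' row for row", call. = FALSE)
  if (any(table(labels) < 1L) || nlevels(labels) < 2L)
    stop("need >= 2 levels, each with >= 1 effect", call. = FALSE)
  y <- effects$lnr
  v <- effects$variance
  X <- stats::model.matrix(~ labels - 1)
  tau2 <- .reml_tau2(y, v, X)$tau2
  w <- 1 / (v + tau2)
  per <- lapply(levels(labels), function(l) {
    i <- labels == l
    s <- pool_effects(effects[i, , drop = FALSE], tau2 = tau2, level = level)
    data.frame(level = l, k = sum(i), mu_hat = s$mu_hat, se = s$se,
               ci_low = s$ci_low, ci_high = s$ci_high, p_value = s$p_value,
               ratio = s$ratio, percent_change = s$percent_change,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  wl <- 1 / per$se^2
  grand <- sum(wl * per$mu_hat) / sum(wl)
  q_between <- sum(wl * (per$mu_hat - grand)^2)
  df_between <- nrow(per) - 1L
  # residual heterogeneity about the fixed-effect level means
  w0 <- 1 / v
  b0 <- solve(crossprod(X, w0 * X), crossprod(X, w0 * y))
  qe <- sum(w0 * (y - X %*% b0)^2)
  df_e <- length(y) - nlevels(labels)
  i2 <- if (qe > 0) max(0, qe - df_e) * 100 / qe else 0
  out <- list(q_between = q_between, df_between = df_between,
              p_between = stats::pchisq(q_between, df_between,
                                        lower.tail = FALSE),
              common_tau2 = tau2, i2 = i2,
              p_hetero = stats::pchisq(qe, df_e, lower.tail = FALSE),
              k = length(y), levels = per)
  class(out) <- "subgroup_result"
  out
}

#' @export
print.subgroup_result <- function(x, ...) {
  cat(sprintf("Subgroup analysis: Q_between = %.2f (df = %d, p = %s)\n",
              x$q_between, x$df_between, format.pval(x$p_between, digits = 3)))
  cat(sprintf("  common tau^2 = %.4f, residual I^2 = %.1f%% (p_hetero = %s)\n",
              x$common_tau2, x$i2, format.pval(x$p_hetero, digits = 3)))
  print(x$levels, digits = 4)
  invisible(x)
}

#' Assign a publication year to a 5-year chronology bin
#'
#' The 35-year literature span is broken into seven equal 5-year periods
#' used as a categorical moderator.
#'
#' @param year Integer year(s) in `[1980, 2014]`.
#' @return Factor with levels `"1980-1984"` through `"2010-2014"`.
#' @export
chronology_bin <- function(year) {
  if (any(is.na(year)) || any(year < 1980) || any(year > 2014))
    stop("year must lie in [1980, 2014]", call. = FALSE)
  starts <- seq(1980, 2010, by = 5)
  labs <- paste0(starts, "-", starts + 4)
  cut(year, breaks = c(starts, 2015), labels = labs, right = FALSE)
}
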