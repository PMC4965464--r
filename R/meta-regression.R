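# Weighted meta-regression on the lnR scale with REML between-study
# variance and Knapp-Hartung small-sample inference, plus the derived
# quantities used to summarize moderator effects: the raw average slope
# back-transformation, the R^2 analog, incremental moderator tests,
# Cook's D influence screening, and weighted moderator correlations.

.design_matrix <- function(moderators, k) {
  X <- as.matrix(as.data.frame(moderators))
  if (!is.numeric(X)) stop("moderators must be numeric", call. = FALSE)
  if (nrow(X) != k) stop("moderators must have one row per effect", call. = FALSE)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (anyNA(X))
    stop("moderators contain missing values; apply listwise deletion first",
         call. = FALSE)
  X
}

#' Weighted meta-regression with Knapp-Hartung inference
#'
#' Fits lnR on one or more numeric moderators by weighted least squares
#' with weights `1 / (variance + tau2)`, where tau2 is the REML estimate
#' of residual between-study variance. Coefficient variances are
#' multiplied by the Knapp-Hartung adjustment (weighted residual sum of
#' squares over k - p) and tested against a t distribution with k - p
#' degrees of freedom; the p-value tests whether the slope is 0.
#'
#' Also reports residual heterogeneity (I^2 and its chi-square p-value),
#' and the R^2 analog: the share of the intercept-only model's tau^2
#' explained by the moderators (undefined when that total tau^2 is 0).
#'
#' @param effects Data frame with columns `lnr`, `variance` and optionally
#'   `study_id`.
#' @param moderators Numeric vector, matrix or data frame of moderator
#'   values, complete (no `NA`) and with one row per effect.
#' @param level Confidence level for coefficient intervals.
#' @return Object of class `"meta_regression"` with elements `coef` (a
#'   per-coefficient data frame: estimate, se, t, p, ci), `tau2`,
#'   `tau2_total`, `r2_analog`, `i2`, `p_hetero`, `k`, `kh_factor`, and
#'   the fitting ingredients (`y`, `v`, `X`, `w`) used by
#'   [cooks_distance()].
#' @export
fit_meta_regression <- function(effects, moderators, level = 0.95) {
  effects <- .check_effects(effects, min_k = 2L)
  y <- effects$lnr
  v <- effects$variance
  k <- length(y)
  X <- cbind(intercept = 1, .design_matrix(moderators, k))
  p <- ncol(X)
  if (k < p + 2L)
    stop("need k >= number of coefficients + 2 (k = ", k, ", p = ", p, ")",
         call. = FALSE)
  qrX <- qr(X)
  if (qrX$rank < p) {
    dep <- colnames(X)[qrX$pivot[seq(qrX$rank + 1L, p)]]
    stop("rank-deficient design; collinear moderators: ",
         paste(dep, collapse = ", "), call. = FALSE)
  }
  tau2 <- .reml_tau2(y, v, X)$tau2
  w <- 1 / (v + tau2)
  A <- crossprod(X, w * X)
  Ainv <- solve(A)
  beta <- as.numeric(Ainv %*% crossprod(X, w * y))
  names(beta) <- colnames(X)
  e <- y - as.numeric(X %*% beta)
  kh <- sum(w * e^2) / (k - p)          # Knapp-Hartung variance adjustment
  se <- sqrt(kh * diag(Ainv))
  tstat <- beta / se
  pval <- 2 * stats::pt(-abs(tstat), df = k - p)
  tq <- stats::qt(1 - (1 - level) / 2, df = k - p)
  coef <- data.frame(term = colnames(X), estimate = beta, se = se,
                     t = tstat, p = pval,
                     ci_low = beta - tq * se, ci_high = beta + tq * se,
                     row.names = NULL, stringsAsFactors = FALSE)
  # residual heterogeneity about the fixed-effect (weights 1/v) fit
  w0 <- 1 / v
  b0 <- solve(crossprod(X, w0 * X), crossprod(X, w0 * y))
  qe <- sum(w0 * (y - X %*% b0)^2)
  df_e <- k - p
  i2 <- if (qe > 0) max(0, qe - df_e) * 100 / qe else 0
  tau2_total <- .reml_tau2(y, v)$tau2
  out <- list(coef = coef, tau2 = tau2, tau2_total = tau2_total,
              r2_analog = r2_analog(tau2, tau2_total),
              i2 = i2, p_hetero = stats::pchisq(qe, df_e, lower.tail = FALSE),
              k = k, p = p, kh_factor = kh, df = k - p,
              y = y, v = v, X = X, w = w,
              study_id = if ("study_id" %in% names(effects))
                effects$study_id else as.character(seq_len(k)))
  class(out) <- "meta_regression"
  out
}

#' @export
print.meta_regression <- function(x, ...) {
  cat(sprintf("Meta-regression (k = %d, REML tau^2 = %.4f, KH t with %d df)\n",
              x$k, x$tau2, x$df))
  print(x$coef, digits = 4)
  cat(sprintf("Residual I^2 = %.1f%% (p_hetero = %s); R^2 analog = %s\n",
              x$i2, format.pval(x$p_hetero, digits = 3),
              if (is.na(x$r2_analog)) "-" else sprintf("%.1f%%", x$r2_analog)))
  invisible(x)
}

#' Raw average slope over a moderator range
#'
#' Back-transforms an lnR-scale regression line to the response-ratio
#' scale and averages its slope across the moderator range:
#' `(exp(slope * maxX + intercept) - exp(slope * minX + intercept)) /
#' (maxX - minX)`. This expresses a moderator effect as the average raw
#' change in the response ratio per unit moderator.
#'
#' @param intercept_lnr,slope_lnr Coefficients on the lnR scale.
#' @param min_x,max_x Moderator range; `max_x > min_x`.
#' @return The raw average slope; its sign equals `sign(slope_lnr)`.
#' @export
average_raw_slope <- function(intercept_lnr, slope_lnr, min_x, max_x) {
  if (any(max_x <= min_x))
    stop("'max_x' must exceed 'min_x'", call. = FALSE)
  (exp(slope_lnr * max_x + intercept_lnr) -
     exp(slope_lnr * min_x + intercept_lnr)) / (max_x - min_x)
}

#' R-squared analog for meta-regression
#'
#' Share of the true (between-study) variance explained by the
#' moderators: `(tau2_total - tau2_residual) / tau2_total * 100`,
#' truncated to `[0, 100]`. Undefined (returned as `NA`) when the
#' moderator-free tau^2 is 0, since there is then no true variance to
#' explain.
#'
#' @param tau2_residual Residual tau^2 from the moderator model.
#' @param tau2_total tau^2 from the intercept-only model on the same
#'   studies.
#' @return Percent in `[0, 100]`, or `NA_real_`.
#' @export
r2_analog <- function(tau2_residual, tau2_total) {
  if (tau2_total <= 0) return(NA_real_)
  min(100, max(0, (tau2_total - tau2_residual) / tau2_total * 100))
}

#' Incremental (test-of-change) moderator test
#'
#' Tests whether one moderator explains variation beyond the others by a
#' Knapp-Hartung-adjusted F test of its coefficient in the full model:
#' F = t^2 on (1, k - p) degrees of freedom, equivalent to the two-sided
#' t test of that coefficient. Intended for the complete-case subset with
#' all moderators present.
#'
#' @param effects Data frame with columns `lnr`, `variance`.
#' @param moderators Data frame or matrix containing all moderators,
#'   complete cases only.
#' @param target Column name of the moderator under test.
#' @return List with `p_test`, `f`, `df1`, `df2` and the full `fit`.
#' @export
incremental_moderator_test <- function(effects, moderators, target) {
  moderators <- as.data.frame(moderators)
  if (!target %in% names(moderators))
    stop("target moderator '", target, "' not in moderator set", call. = FALSE)
  fit <- fit_meta_regression(effects, moderators)
  row <- fit$coef[fit$coef$term == target, ]
  f <- row$t^2
  list(p_test = stats::pf(f, 1, fit$df, lower.tail = FALSE),
       f = f, df1 = 1L, df2 = fit$df, fit = fit)
}

#' Cook's distance for a fitted meta-regression
#'
#' Per-study influence from weighted leverage and residual:
#' `D_i = r_i^2 h_ii / (p (1 - h_ii)^2)` with internally studentized
#' weighted residuals and the Knapp-Hartung residual variance. Studies
#' are flagged when `D > threshold` (default 4/k).
#'
#' @param fit A `"meta_regression"` object.
#' @param threshold Flagging cutoff; default `4 / k`.
#' @return Data frame of class `"influence_report"`: `study_id`,
#'   `cooks_d`, `flagged`.
#' @export
cooks_distance <- function(fit, threshold = NULL) {
  stopifnot(inherits(fit, "meta_regression"))
  if (is.null(threshold)) threshold <- 4 / fit$k
  sw <- sqrt(fit$w)
  Xs <- sw * fit$X
  Ainv <- solve(crossprod(Xs))
  h <- rowSums((Xs %*% Ainv) * Xs)
  es <- sw * (fit$y - as.numeric(fit$X %*% fit$coef$estimate))
  s2 <- fit$kh_factor
  if (s2 < .Machine$double.eps) {
    # numerically exact fit: zero residuals, zero influence by convention
    d <- rep(0, fit$k)
  } else {
    r2 <- es^2 / (s2 * pmax(1 - h, .Machine$double.eps))
    d <- r2 * h / (fit$p * pmax(1 - h, .Machine$double.eps))
  }
  out <- data.frame(study_id = fit$study_id, cooks_d = d,
                    flagged = d > threshold, stringsAsFactors = FALSE)
  class(out) <- c("influence_report", "data.frame")
  out
}

#' Weighted correlations among regression moderators
#'
#' Pairwise-complete weighted Pearson correlations between moderator
#' columns, using meta-analytic weights, with two-sided p-values from the
#' t approximation on (n - 2) degrees of freedom where n counts complete
#' pairs. Cells with fewer than 3 complete pairs are `NA`.
#'
#' @param moderators Data frame of numeric moderator columns (may contain
#'   `NA`).
#' @param weights Positive weights, one per row; typically
#'   `1 / (variance + tau2)` from an intercept-only random-effects model.
#' @return List of class `"moderator_correlation"` with matrices `r`, `p`,
#'   `n`.
#' @export
weighted_moderator_correlation <- function(moderators, weights) {
  M <- as.data.frame(moderators)
  nm <- names(M)
  q <- length(nm)
  if (length(weights) != nrow(M) || any(weights <= 0, na.rm = TRUE))
    stop("'weights' must be positive, one per row", call. = FALSE)
  r <- p <- n <- matrix(NA_real_, q, q, dimnames = list(nm, nm))
  for (i in seq_len(q)) {
    for (j in i:q) {
      ok <- stats::complete.cases(M[[i]], M[[j]], weights)
      n[i, j] <- n[j, i] <- sum(ok)
      if (sum(ok) < 3L) next
      wt <- weights[ok] / sum(weights[ok])
      x <- M[[i]][ok]
      y <- M[[j]][ok]
      mx <- sum(wt * x); my <- sum(wt * y)
      cxy <- sum(wt * (x - mx) * (y - my))
      vx <- sum(wt * (x - mx)^2); vy <- sum(wt * (y - my)^2)
      if (vx <= 0 || vy <= 0) next
      rij <- cxy / sqrt(vx * vy)
      rij <- min(1, max(-1, rij))
      r[i, j] <- r[j, i] <- rij
      nn <- sum(ok)
      tt <- rij * sqrt((nn - 2) / max(1 - rij^2, .Machine$double.eps))
      p[i, j] <- p[j, i] <- 2 * stats::pt(-abs(tt), df = nn - 2)
    }
  }
  out <- list(r = r, p = p, n = n)
  class(out) <- "moderator_correlation"
  out
}

#' @export
print.moderator_correlation <- function(x, ...) {
  stars <- ifelse(is.na(x$p), "", ifelse(x$p < 0.001, "***",
                  ifelse(x$p < 0.01, "**", ifelse(x$p < 0.05, "*", ""))))
  disp <- matrix(paste0(ifelse(is.na(x$r), "-", sprintf("%.3f", x$r)), stars),
                 nrow(x$r), dimnames = dimnames(x$r))
  print(disp, quote = FALSE)
  invisible(x)
}
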