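# Publication-bias diagnostics and leave-one-out sensitivity analysis.

#' Begg-Mazumdar rank correlation test for publication bias
#'
#' Kendall rank correlation between variance-stabilized effect deviates
#' and their variances. Effects are centered at the fixed-effect pooled
#' mean and divided by their conditional standard errors
#' `sqrt(v_i - 1/sum(1/v))`; the tie-corrected tau is tested with the
#' normal approximation. A tau near 0 indicates no tendency for effects
#' to grow as studies get smaller.
#'
#' @param effects Data frame with columns `lnr` and `variance` (k >= 3).
#' @return List of class `"begg_mazumdar"`: `tau`, `p`, `k`.
#' @export
begg_mazumdar <- function(effects) {
  effects <- .check_effects(effects, min_k = 3L)
  v <- effects$variance
  w <- 1 / v
  mu_f <- sum(w * effects$lnr) / sum(w)
  v_star <- pmax(v - 1 / sum(w), .Machine$double.eps)
  dev <- (effects$lnr - mu_f) / sqrt(v_star)
  ct <- suppressWarnings(
    stats::cor.test(dev, v, method = "kendall", exact = FALSE))
  out <- list(tau = unname(ct$estimate), p = ct$p.value, k = nrow(effects))
  class(out) <- "begg_mazumdar"
  out
}

#' @export
print.begg_mazumdar <- function(x, ...) {
  cat(sprintf("Begg-Mazumdar rank correlation: tau = %.3f, p = %s (k = %d)\n",
              x$tau, format.pval(x$p, digits = 3), x$k))
  invisible(x)
}

#' Funnel-plot data
#'
#' One point per study: effect size against its standard error, ordered by
#' standard error, for external plotting.
#'
#' @param effects Data frame with columns `lnr`, `variance` and optionally
#'   `study_id`.
#' @return Data frame with columns `study_id`, `lnr`, `se`, ordered by
#'   `se`.
#' @export
funnel_data <- function(effects) {
  effects <- .check_effects(effects, min_k = 1L)
  out <- data.frame(
    study_id = if ("study_id" %in% names(effects)) effects$study_id
               else as.character(seq_len(nrow(effects))),
    lnr = effects$lnr, se = sqrt(effects$variance),
    stringsAsFactors = FALSE)
  out[order(out$se), , drop = FALSE]
}

#' Leave-one-out sensitivity analysis
#'
#' Omits each study in turn, re-estimates tau^2 by REML on the remaining
#' k - 1 studies, and re-pools. Influence is reported on the response-
#' ratio scale: the per-omission pooled ratio, its percent change from
#' the full-sample ratio, the maximum absolute ratio change, and the
#' identity of the most influential study.
#'
#' @param effects Data frame with columns `lnr`, `variance` and optionally
#'   `study_id` (k >= 2).
#' @param level Confidence level for per-omission intervals.
#' @return Data frame of class `"sensitivity_trace"` (one row per omitted
#'   study: `omitted_study`, `mu_hat`, `ratio`, `ci_low_ratio`,
#'   `ci_high_ratio`, `pct_change_from_full`) with attributes `full`
#'   (the full-sample [pool_effects()] summary), `max_abs_change` and
#'   `most_influential_study`.
#' @export
leave_one_out <- function(effects, level = 0.95) {
  effects <- .check_effects(effects, min_k = 2L)
  k <- nrow(effects)
  ids <- if ("study_id" %in% names(effects)) effects$study_id
         else as.character(seq_len(k))
  full <- pool_effects(effects, level = level)
  rows <- lapply(seq_len(k), function(i) {
    rest <- effects[-i, , drop = FALSE]
    s <- pool_effects(rest, level = level)
    data.frame(omitted_study = ids[i], mu_hat = s$mu_hat, ratio = s$ratio,
               ci_low_ratio = exp(s$ci_low), ci_high_ratio = exp(s$ci_high),
               pct_change_from_full = (s$ratio / full$ratio - 1) * 100,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  delta <- abs(out$ratio - full$ratio)
  attr(out, "full") <- full
  attr(out, "max_abs_change") <- max(delta)
  attr(out, "most_influential_study") <- out$omitted_study[which.max(delta)]
  class(out) <- c("sensitivity_trace", "data.frame")
  out
}

#' @export
print.sensitivity_trace <- function(x, ...) {
  full <- attr(x, "full")
  cat(sprintf("Leave-one-out over k = %d studies; full ratio = %.3f\n",
              nrow(x), full$ratio))
  cat(sprintf("Most influential: %s (max |ratio change| = %.4f)\n",
              attr(x, "most_influential_study"), attr(x, "max_abs_change")))
  invisible(x)
}
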