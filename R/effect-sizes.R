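# Per-study effect-size and variance primitives for AM-vs-NM gas-exchange
# meta-analysis. The unit of analysis is the natural-log response ratio
# lnR = ln(Y_AM / Y_NM) of treatment means, weighted by a non-parametric
# (sample-size only) variance because most plant gas-exchange papers omit
# dispersion measures.

#' Log response ratio of AM to NM treatment means
#'
#' Computes `ln(am_mean / nm_mean)`, the effect size used throughout the
#' package. Both means must be strictly positive; apply [floor_adjust()]
#' first when a study contains zero or negative gas-exchange values.
#'
#' @param am_mean Numeric vector of arbuscular-mycorrhizal treatment means.
#' @param nm_mean Numeric vector of non-mycorrhizal control means.
#' @param study_id Optional study label(s), used only in error messages.
#' @return Numeric vector of log response ratios. Antisymmetric:
#'   `compute_lnr(a, b) == -compute_lnr(b, a)`.
#' @examples
#' compute_lnr(1.49, 1.0)   # 0.399: a 49% AM stimulation
#' @export
compute_lnr <- function(am_mean, nm_mean, study_id = NULL) {
  bad <- !is.finite(am_mean) | !is.finite(nm_mean) | am_mean <= 0 | nm_mean <= 0
  if (any(bad)) {
    lab <- if (is.null(study_id)) which(bad) else rep_len(study_id, length(bad))[bad]
    stop("non-positive or missing treatment mean for study: ",
         paste(unique(lab), collapse = ", "),
         " (apply floor_adjust() before computing lnR)", call. = FALSE)
  }
  log(am_mean / nm_mean)
}

#' Floor adjustment for zero and negative gas-exchange values
#'
#' Zero gas-exchange readings are biologically common but a ratio cannot be
#' formed from them. Within one study, negative values are first set to 0,
#' then every value below `floor_fraction` times the study's maximum is
#' raised to exactly that floor (1% of the maximum by default). Values at
#' or above the floor, including the maximum, are unchanged, so the
#' operation is idempotent.
#'
#' @param values Numeric vector: all reported values of one outcome within
#'   one study (both treatments, all time-points pooled).
#' @param floor_fraction Fraction of the study maximum used as the floor.
#' @return Adjusted numeric vector, strictly positive.
#' @export
floor_adjust <- function(values, floor_fraction = 0.01) {
  if (length(values) == 0L || anyNA(values))
    stop("'values' must be non-empty and complete", call. = FALSE)
  values[values < 0] <- 0
  if (all(values <= 0))
    stop("all gas-exchange values are <= 0; study unusable for ratio analysis",
         call. = FALSE)
  floor <- floor_fraction * max(values)
  values[values < floor] <- floor
  values
}

#' Non-parametric within-study variance of lnR
#'
#' Variance of the log response ratio computed from sample sizes alone,
#' `(n_am + n_nm) / (n_am * n_nm)`, used when studies report sample sizes
#' but no dispersion measure.
#'
#' @param n_am,n_nm Sample sizes (>= 1) of the AM and NM treatments.
#' @return Positive numeric vector; symmetric in its arguments.
#' @export
nonparametric_variance <- function(n_am, n_nm) {
  if (any(!is.finite(n_am)) || any(!is.finite(n_nm)) ||
      any(n_am < 1) || any(n_nm < 1))
    stop("sample sizes must be >= 1 (resolve them first)", call. = FALSE)
  (n_am + n_nm) / (n_am * n_nm)
}

#' Variance of a multi-time-point synthetic effect size
#'
#' When a study reports the same outcome at m time-points the per-study
#' effect is the mean across time-points, with variance
#' `v * (1 + (m - 1) * r) / m` where `r` is the correlation among
#' time-points. At `r = 1` repeated measurements carry no new information
#' and the variance equals the single-time-point value `v`; at `r = 0` it
#' is `v / m`.
#'
#' @param v Single-time-point variance (from [nonparametric_variance()]).
#' @param m Number of time-points (>= 1).
#' @param r Correlation among time-points, in `[0, 1]`.
#' @return Positive numeric vector.
#' @export
timepoint_variance <- function(v, m, r) {
  if (any(r < 0) || any(r > 1)) stop("'r' must lie in [0, 1]", call. = FALSE)
  if (any(v <= 0)) stop("'v' must be positive", call. = FALSE)
  if (any(m < 1)) stop("'m' must be >= 1", call. = FALSE)
  v * (1 + (m - 1) * r) / m
}

#' Collapse a study's time-points into one effect size
#'
#' The per-study lnR is the arithmetic mean of the per-time-point lnR
#' values, and its variance is [timepoint_variance()] applied to the
#' non-parametric variance of the study's sample sizes. Means must already
#' be floor-adjusted.
#'
#' @param am_means,nm_means Numeric vectors of per-time-point treatment
#'   means (equal length, strictly positive).
#' @param n_am,n_nm Resolved sample sizes.
#' @param r Time-point correlation (default 0.1, the constant applied to
#'   all studies in the gas-exchange setting).
#' @param study_id,outcome Optional labels carried into the result.
#' @return One-row data frame with columns `study_id`, `outcome`, `lnr`,
#'   `variance`, `m`.
#' @export
aggregate_timepoints <- function(am_means, nm_means, n_am, n_nm, r = 0.1,
                                 study_id = NA_character_,
                                 outcome = NA_character_) {
  if (length(am_means) != length(nm_means) || length(am_means) == 0L)
    stop("'am_means' and 'nm_means' must be non-empty and of equal length",
         call. = FALSE)
  lnr_t <- compute_lnr(am_means, nm_means, study_id = study_id)
  m <- length(lnr_t)
  v1 <- nonparametric_variance(n_am, n_nm)
  data.frame(study_id = as.character(study_id), outcome = as.character(outcome),
             lnr = mean(lnr_t), variance = timepoint_variance(v1, m, r), m = m,
             stringsAsFactors = FALSE)
}

#' Resolve a reported sample size
#'
#' Applies the conservative imputation rules for incompletely reported
#' sample sizes: a range resolves to its smallest value; a missing sample
#' size resolves to 2 when an LSD or standard error was reported (some
#' replication must have existed) and to 1 otherwise; a reported scalar is
#' returned as is.
#'
#' @param n Reported sample size: a scalar, a length-2 numeric range, a
#'   string such as `"4-6"`, or `NA`.
#' @param dispersion One of `"none"`, `"lsd_or_se"`, `"full"`: what
#'   dispersion information the study reported.
#' @return A single count >= 1.
#' @export
resolve_sample_size <- function(n, dispersion = c("none", "lsd_or_se", "full")) {
  dispersion <- match.arg(dispersion)
  if (is.character(n) && length(n) == 1L && !is.na(n)) {
    parts <- suppressWarnings(as.numeric(strsplit(n, "[-–]")[[1]]))
    n <- if (all(is.finite(parts))) parts else NA_real_
  }
  if (length(n) == 0L || all(is.na(n)))
    return(if (dispersion == "none") 1L else 2L)
  n <- n[!is.na(n)]
  as.integer(min(n))
}

#' Midpoint of a reported colonization range
#'
#' Root colonization reported as a narrow range (at most 25 percentage
#' points) resolves to the midpoint; wider ranges are too vague to impute
#' and return `NA` so the study is excluded from colonization regressions.
#'
#' @param lo,hi Range endpoints in percent, `0 <= lo <= hi <= 100`.
#' @return Midpoint percent, or `NA_real_` for ranges wider than 25 points.
#' @export
colonization_from_range <- function(lo, hi) {
  if (any(lo < 0) || any(hi > 100) || any(lo > hi))
    stop("need 0 <= lo <= hi <= 100", call. = FALSE)
  out <- (lo + hi) / 2
  out[hi - lo > 25] <- NA_real_
  out
}

#' Back-transform lnR to a raw percentage change
#'
#' @param lnr Log response ratio(s).
#' @return `(exp(lnr) - 1) * 100`, the percent increase of the AM treatment
#'   over the NM control.
#' @export
percent_change <- function(lnr) (exp(lnr) - 1) * 100

#' Estimate the time-point correlation from repeated-measures data
#'
#' Given per-experimental-unit measurements at several time-points,
#' returns the average pairwise Pearson correlation across time-points,
#' truncated to `[0, 1]`. Used to choose the `r` constant entering
#' [timepoint_variance()]; in published gas-exchange datasets this
#' correlation is close to 0 and the analyses default to `r = 0.1`.
#'
#' @param x Numeric matrix, rows = experimental units (>= 3),
#'   columns = time-points (>= 2).
#' @return Scalar correlation in `[0, 1]`.
#' @export
estimate_timepoint_correlation <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2L || nrow(x) < 3L)
    stop("need >= 2 time-points and >= 3 experimental units", call. = FALSE)
  cm <- stats::cor(x, use = "pairwise.complete.obs")
  r <- mean(cm[upper.tri(cm)])
  min(max(r, 0), 1)
}
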