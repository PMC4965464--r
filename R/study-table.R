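# Study-table ingestion and normalization. The interchange format is a
# delimited table with one row per (study x outcome x time-point); the
# normalized analysis object is one effect size per (study x outcome).

#' Read a study table from CSV
#'
#' One row per (study, outcome, time-point); empty fields are missing
#' values. See [as_study_table()] for the column contract.
#'
#' @param path Path to a CSV file.
#' @return A validated study-table data frame.
#' @export
read_study_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  as_study_table(df)
}

#' Validate a data frame as a study table
#'
#' Checks column presence and types, the outcome / dispersion / stress
#' enums, and moderator ranges (colonization in `[0, 100]`, effect-size
#' ratios strictly positive when present).
#'
#' @param df A data frame with the study-table columns.
#' @return The data frame, with enum columns normalized, classed
#'   `"study_table"`.
#' @export
as_study_table <- function(df) {
  missing_cols <- setdiff(.STUDY_COLS, names(df))
  if (length(missing_cols))
    stop("study table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  df$study_id <- as.character(df$study_id)
  df$outcome <- toupper(as.character(df$outcome))
  if (!all(df$outcome %in% .OUTCOMES))
    stop("outcome must be one of ", paste(.OUTCOMES, collapse = ", "),
         call. = FALSE)
  if (!all(is.na(df$dispersion_reported) |
           df$dispersion_reported %in% c("none", "lsd_or_se", "full")))
    stop("dispersion_reported must be none, lsd_or_se or full", call. = FALSE)
  if (!all(is.na(df$stress) | df$stress %in% c("stressed", "unstressed")))
    stop("stress must be coded stressed/unstressed", call. = FALSE)
  ok_col <- is.na(df$colonization_pct) |
    (df$colonization_pct >= 0 & df$colonization_pct <= 100)
  if (!all(ok_col))
    stop("colonization_pct outside [0, 100] for study: ",
         paste(unique(df$study_id[!ok_col]), collapse = ", "), call. = FALSE)
  for (mc in c("shoot_dw_es", "leaf_p_es", "nm_leaf_np", "leaf_np_es")) {
    bad <- !is.na(df[[mc]]) & df[[mc]] <= 0
    if (any(bad))
      stop(mc, " must be strictly positive when present (study ",
           paste(unique(df$study_id[bad]), collapse = ", "), ")", call. = FALSE)
  }
  bad_year <- !is.na(df$year) & (df$year != round(df$year) | df$year < 1)
  if (any(bad_year)) stop("year must be a positive integer", call. = FALSE)
  class(df) <- c("study_table", "data.frame")
  df
}

#' Normalize a study table into per-study effect sizes
#'
#' For every (study, outcome) pair: resolves sample sizes (range minimum;
#' n = 1 for missing n without dispersion information, n = 2 when an LSD
#' or SE was reported), floor-adjusts all of the study's values of that
#' outcome jointly across treatments and time-points, computes the
#' per-time-point lnR, averages time-points, and attaches the
#' multi-time-point non-parametric variance. Studies whose values are all
#' non-positive are dropped with a warning.
#'
#' @param studies A study table (see [as_study_table()]).
#' @param r Time-point correlation constant (default 0.1).
#' @param floor_fraction Floor for the zero adjustment, as a fraction of
#'   the study maximum (default 0.01).
#' @return Data frame of class `"effect_table"` with one row per
#'   (study, outcome): `study_id`, `outcome`, `lnr`, `variance`, `m`,
#'   moderators, `stress`, `year`, and resolved `n_am`, `n_nm`. The number
#'   of studies that needed sample-size imputation or floor adjustment is
#'   recorded in attributes `n_imputed` and `n_floored`.
#' @export
effect_table <- function(studies, r = 0.1, floor_fraction = 0.01) {
  studies <- as_study_table(as.data.frame(studies))
  key <- interaction(studies$study_id, studies$outcome, drop = TRUE)
  groups <- split(seq_len(nrow(studies)), key)
  rows <- vector("list", length(groups))
  dropped <- character(0)
  n_imputed <- 0L
  n_floored <- 0L
  for (g in seq_along(groups)) {
    idx <- groups[[g]]
    s <- studies[idx, , drop = FALSE]
    disp <- s$dispersion_reported[1]
    if (is.na(disp)) disp <- "none"
    imput <- is.na(s$n_am[1]) || is.na(s$n_nm[1])
    n_am <- resolve_sample_size(s$n_am[1], disp)
    n_nm <- resolve_sample_size(s$n_nm[1], disp)
    if (imput) n_imputed <- n_imputed + 1L
    vals <- c(s$am_mean, s$nm_mean)
    if (anyNA(vals)) {
      dropped <- c(dropped, s$study_id[1])
      next
    }
    adj <- tryCatch(floor_adjust(vals, floor_fraction), error = function(e) NULL)
    if (is.null(adj)) {
      dropped <- c(dropped, s$study_id[1])
      next
    }
    if (!identical(adj, vals)) n_floored <- n_floored + 1L
    m <- nrow(s)
    es <- aggregate_timepoints(adj[seq_len(m)], adj[m + seq_len(m)],
                               n_am, n_nm, r = r,
                               study_id = s$study_id[1], outcome = s$outcome[1])
    es$n_am <- n_am
    es$n_nm <- n_nm
    for (mc in .MODERATORS) es[[mc]] <- s[[mc]][1]
    es$stress <- s$stress[1]
    es$year <- s$year[1]
    rows[[g]] <- es
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (length(dropped))
    warning("dropped unusable studies (all values <= 0 or incomplete): ",
            paste(unique(dropped), collapse = ", "), call. = FALSE)
  if (is.null(out))
    stop("no usable studies in table", call. = FALSE)
  rownames(out) <- NULL
  attr(out, "r") <- r
  attr(out, "n_imputed") <- n_imputed
  attr(out, "n_floored") <- n_floored
  class(out) <- c("effect_table", "data.frame")
  out
}

#' Write the normalized effect-size table to CSV
#'
#' @param effects An effect table from [effect_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_effect_table <- function(effects, path) {
  utils::write.csv(as.data.frame(effects), path, row.names = FALSE)
  invisible(path)
}
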