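#' Plausibility exclusion range
#'
#' Values strictly below `low` or strictly above `high` are implausible
#' ("flags") and excluded before moment estimation; the endpoints themselves
#' are kept.
#'
#' @param low,high Bounds in g/dL, defaults 4.0 and 18.0.
#' @return A list of class `exclusion_policy`.
#' @export
exclusion_policy <- function(low = 4.0, high = 18.0) {
  stopifnot(low < high)
  structure(list(low = low, high = high), class = "exclusion_policy")
}

#' Outlier tabulation cutoffs
#'
#' @param low Lower cutoffs in g/dL, default `c(4, 5, 6)`.
#' @param high Upper cutoffs in g/dL, default `c(16, 17, 18)`.
#' @return A list of class `outlier_cutoffs`.
#' @export
outlier_cutoffs <- function(low = c(4, 5, 6), high = c(16, 17, 18)) {
  stopifnot(max(low) < min(high))
  structure(list(low = low, high = high), class = "outlier_cutoffs")
}

#' Apply the plausibility exclusion to a value vector
#'
#' @param x Numeric Hb values (g/dL).
#' @param policy An [exclusion_policy()].
#' @return List with `kept` (values in \[low, high\]), `n_excluded_low` and
#'   `n_excluded_high`.
#' @export
apply_exclusion <- function(x, policy = exclusion_policy()) {
  lo <- x < policy$low
  hi <- x > policy$high
  list(kept = x[!lo & !hi],
       n_excluded_low = sum(lo),
       n_excluded_high = sum(hi))
}

#' Percentage of values beyond a cutoff
#'
#' Strict inequality on the named side, expressed as a percentage of all
#' supplied values.
#'
#' @param x Numeric vector, n >= 1.
#' @param cutoff Cutoff in g/dL.
#' @param side `"below"` or `"above"`.
#' @return Percentage in \[0, 100\]; `NA` for empty input.
#' @export
outlier_fraction <- function(x, cutoff, side = c("below", "above")) {
  side <- match.arg(side)
  if (length(x) == 0) return(NA_real_)
  hits <- if (side == "below") x < cutoff else x > cutoff
  100 * sum(hits) / length(x)
}

#' Categorize a survey's outlier prevalence
#'
#' Three mutually exclusive categories: `none` (exactly 0%), `upto1`
#' ((0, 1\]%), `gt1` (> 1%). A survey at exactly 1% falls in `upto1`.
#'
#' @param pct Outlier percentage(s) in \[0, 100\].
#' @return Factor with levels `none`, `upto1`, `gt1`.
#' @export
categorize_outliers <- function(pct) {
  stopifnot(all(pct >= 0 & pct <= 100, na.rm = TRUE))
  cut(pct, breaks = c(-Inf, 0, 1, Inf), labels = c("none", "upto1", "gt1"))
}

#' Tabulate outlier flags across cutoffs for one demographic group
#'
#' Record-level percentages pool all valid records (each record weighted
#' equally); survey-level rows give the percentage of surveys whose own
#' outlier share falls in each prevalence category. A combined
#' "< low or > high" column uses the exclusion policy's bounds.
#'
#' @param records Validity-marked records tibble for one group (or a
#'   corpus; pass `group` to filter).
#' @param group Optional group to filter to (`"child"` or `"wra"`).
#' @param cutoffs An [outlier_cutoffs()].
#' @param policy An [exclusion_policy()] defining the combined column.
#' @return Tibble with one row per cutoff column: `cutoff_label`,
#'   `record_pct`, `surveys_none_pct`, `surveys_0to1_pct`,
#'   `surveys_gt1_pct`, plus `n_records` and `n_surveys` attributes repeated
#'   as columns.
#' @export
tabulate_flags <- function(records, group = NULL,
                           cutoffs = outlier_cutoffs(),
                           policy = exclusion_policy()) {
  stopifnot("hb_valid" %in% names(records))
  if (!is.null(group)) records <- records[records$group == group, ]
  valid <- records[records$hb_valid, , drop = FALSE]
  if (nrow(valid) == 0) stop("no valid records to tabulate", call. = FALSE)
  x <- valid$hb_gdl
  by_survey <- split(x, valid$survey_id)
  n_surveys <- length(by_survey)

  spec <- c(
    lapply(cutoffs$low, function(co) list(
      label = sprintf("<%.1f", co),
      fn = function(v) outlier_fraction(v, co, "below"))),
    lapply(cutoffs$high, function(co) list(
      label = sprintf(">%.1f", co),
      fn = function(v) outlier_fraction(v, co, "above"))),
    list(list(
      label = sprintf("<%.1f or >%.1f", policy$low, policy$high),
      fn = function(v) outlier_fraction(v, policy$low, "below") +
        outlier_fraction(v, policy$high, "above")))
  )

  rows <- lapply(spec, function(s) {
    per_survey <- vapply(by_survey, s$fn, numeric(1))
    cat3 <- table(categorize_outliers(per_survey))
    tibble::tibble(
      cutoff_label = s$label,
      record_pct = s$fn(x),
      surveys_none_pct = 100 * cat3[["none"]] / n_surveys,
      surveys_0to1_pct = 100 * cat3[["upto1"]] / n_surveys,
      surveys_gt1_pct = 100 * cat3[["gt1"]] / n_surveys,
      n_records = length(x),
      n_surveys = n_surveys
    )
  })
  dplyr::bind_rows(rows)
}
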