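#' Column schema for hemoglobin record CSV files
#'
#' Maps the canonical record fields to the column names used in an input
#' file. Only `survey_id`, `group` and `hb_gdl` are mandatory; the rest are
#' picked up when present.
#'
#' @param survey_id,group,hb_gdl Mandatory column names.
#' @param record_id,country,site,year,pregnant,altitude_m,altitude_adjusted
#'   Optional column names.
#' @return A named list of class `hb_schema`.
#' @export
hb_schema <- function(survey_id = "survey_id", group = "group",
                      hb_gdl = "hb_gdl", record_id = "record_id",
                      country = "country", site = "site", year = "year",
                      pregnant = "pregnant", altitude_m = "altitude_m",
                      altitude_adjusted = "altitude_adjusted") {
  structure(list(
    survey_id = survey_id, group = group, hb_gdl = hb_gdl,
    record_id = record_id, country = country, site = site, year = year,
    pregnant = pregnant, altitude_m = altitude_m,
    altitude_adjusted = altitude_adjusted
  ), class = "hb_schema")
}

#' Survey inclusion policy
#'
#' A survey enters the analysis only if at least `min_valid_fraction` of the
#' individuals sampled for Hb have a valid measurement (the 30% floor
#' accommodates anemia sub-sampling designs) and at least `min_n_valid`
#' valid values exist. Validity itself is the analyzer reporting range.
#'
#' @param min_valid_fraction Minimum proportion of sampled individuals with a
#'   valid Hb value. Default 0.30.
#' @param min_n_valid Minimum number of valid values. Default 1.
#' @param validity_range Valid analyzer reporting range in g/dL, inclusive at
#'   both ends. Default `c(0, 25.6)` (HemoCue Hb 301).
#' @return A list of class `inclusion_policy`.
#' @export
inclusion_policy <- function(min_valid_fraction = 0.30, min_n_valid = 1,
                             validity_range = c(0, 25.6)) {
  stopifnot(min_valid_fraction > 0, min_valid_fraction <= 1,
            min_n_valid >= 0, length(validity_range) == 2,
            validity_range[1] < validity_range[2])
  structure(list(min_valid_fraction = min_valid_fraction,
                 min_n_valid = min_n_valid,
                 validity_range = validity_range),
            class = "inclusion_policy")
}

group_levels <- c("child", "wra")

#' Read record-level hemoglobin data from a delimited text file
#'
#' One row per measured individual. Unparseable Hb values become `NA` and the
#' row is retained (it later fails validity marking), so row counts are
#' preserved through ingestion. Pregnant women are dropped at ingestion
#' because the reference ranges apply to non-pregnant women only; a missing
#' pregnancy flag is treated as non-pregnant.
#'
#' @param path Path to a delimited text file with a header row.
#' @param schema An [hb_schema()] mapping canonical fields to file columns.
#' @param delim Field delimiter, default `","`.
#' @param drop_pregnant Drop records flagged pregnant. Default `TRUE`.
#' @return A tibble with columns `record_id`, `survey_id`, `country`, `site`,
#'   `year`, `group`, `hb_gdl`, `altitude_m`, `pregnant`,
#'   `altitude_adjusted`. `hb_valid` is not set here; see [mark_validity()].
#' @export
read_hb_records <- function(path, schema = hb_schema(), delim = ",",
                            drop_pregnant = TRUE) {
  stopifnot(file.exists(path))
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  for (fld in c("survey_id", "group", "hb_gdl")) {
    if (!schema[[fld]] %in% names(raw)) {
      stop("input is missing mandatory column '", schema[[fld]],
           "' (field ", fld, ")", call. = FALSE)
    }
  }
  pick <- function(fld, default = NA_character_) {
    col <- schema[[fld]]
    if (!is.null(col) && col %in% names(raw)) raw[[col]]
    else rep(default, nrow(raw))
  }
  rec <- tibble::tibble(
    record_id = pick("record_id"),
    survey_id = pick("survey_id"),
    country = pick("country"),
    site = pick("site"),
    year = suppressWarnings(as.integer(pick("year"))),
    group = tolower(trimws(pick("group"))),
    hb_gdl = suppressWarnings(as.numeric(pick("hb_gdl"))),
    altitude_m = suppressWarnings(as.numeric(pick("altitude_m"))),
    pregnant = parse_logical_flag(pick("pregnant")),
    altitude_adjusted = parse_logical_flag(pick("altitude_adjusted"),
                                           default = TRUE)
  )
  if (nrow(rec) > 0 && is.na(rec$record_id[1])) {
    rec$record_id <- sprintf("r%06d", seq_len(nrow(rec)))
  }
  bad_grp <- !rec$group %in% group_levels & !is.na(rec$group)
  if (any(bad_grp)) {
    stop("unrecognized group value(s): ",
         paste(unique(rec$group[bad_grp]), collapse = ", "),
         " (expected 'child' or 'wra')", call. = FALSE)
  }
  if (drop_pregnant) {
    preg <- rec$group == "wra" & !is.na(rec$pregnant) & rec$pregnant
    if (any(preg)) {
      message("dropping ", sum(preg), " pregnant WRA record(s) at ingestion")
      rec <- rec[!preg, , drop = FALSE]
    }
  }
  rec
}

parse_logical_flag <- function(x, default = FALSE) {
  out <- rep(default, length(x))
  x <- tolower(trimws(as.character(x)))
  out[x %in% c("true", "t", "1", "yes", "y")] <- TRUE
  out[x %in% c("false", "f", "0", "no", "n")] <- FALSE
  out
}

#' Mark record validity against the analyzer reporting range
#'
#' Adds (or overwrites) a logical `hb_valid` column: `TRUE` iff `hb_gdl` is
#' present and inside the policy's validity range, inclusive at both ends.
#' No records are dropped; the operation is idempotent.
#'
#' @param records A records tibble (see [read_hb_records()]).
#' @param policy An [inclusion_policy()].
#' @return The records tibble with an `hb_valid` column.
#' @export
mark_validity <- function(records, policy = inclusion_policy()) {
  rng <- policy$validity_range
  records$hb_valid <- !is.na(records$hb_gdl) &
    records$hb_gdl >= rng[1] & records$hb_gdl <= rng[2]
  records
}

#' Remove exact-duplicate records
#'
#' A duplicate is a row identical in every field; the first occurrence is
#' kept. Rows sharing a `record_id` but differing elsewhere are retained
#' (dropping a real measurement would change the distribution shape) with a
#' warning.
#'
#' @param records A records tibble.
#' @return The deduplicated tibble, with attribute `n_removed`.
#' @export
dedupe_records <- function(records) {
  dup <- duplicated(records)
  out <- records[!dup, , drop = FALSE]
  if (nrow(out) > 0 && !all(is.na(out$record_id))) {
    id_dup <- duplicated(out[, c("survey_id", "group", "record_id")])
    if (any(id_dup)) {
      warning(sum(id_dup), " record(s) share a record_id within a survey ",
              "but differ in other fields; all kept", call. = FALSE)
    }
  }
  attr(out, "n_removed") <- sum(dup)
  out
}

#' Decide survey inclusion under the valid-fraction rule
#'
#' @param n_valid Number of valid Hb values in the survey.
#' @param n_sampled Number of individuals sampled for Hb. When subsampling
#'   metadata is absent callers pass the record count, which makes the
#'   fraction rule vacuous.
#' @param policy An [inclusion_policy()].
#' @return A list with `include` (logical) and `reason` (character).
#' @export
include_survey <- function(n_valid, n_sampled, policy = inclusion_policy()) {
  if (is.na(n_sampled) || n_sampled == 0) {
    return(list(include = FALSE, reason = "no sample"))
  }
  frac <- n_valid / n_sampled
  if (n_valid < policy$min_n_valid) {
    list(include = FALSE,
         reason = sprintf("only %d valid value(s), need >= %d",
                          n_valid, policy$min_n_valid))
  } else if (frac < policy$min_valid_fraction) {
    list(include = FALSE,
         reason = sprintf("valid fraction %.3f below %.2f",
                          frac, policy$min_valid_fraction))
  } else {
    list(include = TRUE, reason = "included")
  }
}

#' Apply the full inclusion screen to a record corpus
#'
#' Deduplicates, marks validity and evaluates the inclusion rule for every
#' survey-group combination.
#'
#' @param records A records tibble.
#' @param policy An [inclusion_policy()].
#' @param n_sampled Optional named vector of sampled counts keyed by
#'   `survey_id.group`; defaults to per-survey record counts.
#' @return A list with `records` (deduplicated, validity-marked) and
#'   `inclusion` (tibble: survey_id, group, n_records, n_valid, n_sampled,
#'   include, reason).
#' @export
screen_surveys <- function(records, policy = inclusion_policy(),
                           n_sampled = NULL) {
  records <- dedupe_records(records)
  records <- mark_validity(records, policy)
  tab <- dplyr::summarise(
    dplyr::group_by(records, .data$survey_id, .data$group),
    n_records = dplyr::n(),
    n_valid = sum(.data$hb_valid),
    .groups = "drop"
  )
  key <- paste(tab$survey_id, tab$group, sep = ".")
  tab$n_sampled <- if (is.null(n_sampled)) tab$n_records else {
    ifelse(key %in% names(n_sampled), unname(n_sampled[key]), tab$n_records)
  }
  dec <- Map(include_survey, tab$n_valid, tab$n_sampled,
             MoreArgs = list(policy = policy))
  tab$include <- vapply(dec, `[[`, logical(1), "include")
  tab$reason <- vapply(dec, `[[`, character(1), "reason")
  list(records = records, inclusion = tab)
}
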