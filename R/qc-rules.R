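#' Quality-control rule set for survey hemoglobin distributions
#'
#' The proposed per-survey plausibility thresholds: a survey is flagged for
#' quality investigation when its G1 skewness exceeds `skew_max`, its G2
#' excess kurtosis falls below `kurt_min`, its SD lies outside the group's
#' plausible range, or more than `flag_pct_max` percent of its valid values
#' fall outside the exclusion range. Boundary values pass (the comparisons
#' are strict).
#'
#' @param skew_max Maximum plausible G1 skewness, default +0.2.
#' @param kurt_min Minimum plausible G2 excess kurtosis, default -0.5.
#' @param sd_range_child,sd_range_wra Plausible SD ranges in g/dL, defaults
#'   `c(1.1, 1.55)` and `c(1.1, 1.65)`.
#' @param flag_pct_max Maximum plausible percentage of implausible values,
#'   default 1.0.
#' @param exclusion The [exclusion_policy()] defining implausible values.
#' @return A list of class `qc_ruleset`.
#' @export
qc_ruleset <- function(skew_max = 0.2, kurt_min = -0.5,
                       sd_range_child = c(1.1, 1.55),
                       sd_range_wra = c(1.1, 1.65),
                       flag_pct_max = 1.0,
                       exclusion = exclusion_policy()) {
  stopifnot(sd_range_child[1] < sd_range_child[2],
            sd_range_wra[1] < sd_range_wra[2],
            flag_pct_max > 0, flag_pct_max < 100)
  structure(list(skew_max = skew_max, kurt_min = kurt_min,
                 sd_range_child = sd_range_child,
                 sd_range_wra = sd_range_wra,
                 flag_pct_max = flag_pct_max, exclusion = exclusion),
            class = "qc_ruleset")
}

qc_flag_names <- c("SKEW_HIGH", "KURT_LOW", "SD_LOW", "SD_HIGH",
                   "FLAG_PCT_HIGH")

#' Evaluate the QC rules against per-survey statistics
#'
#' Each rule is evaluated independently; the verdict is `investigate` iff at
#' least one rule triggers, `insufficient data` when any required statistic
#' is unavailable (n < 4 or a constant sample).
#'
#' @param stats A per-survey statistics tibble (rows as produced by
#'   [summarize_survey()] / [summarize_surveys()]).
#' @param rules A [qc_ruleset()].
#' @return A tibble with one row per input row: survey_id, group, columns of
#'   the compared values, `triggered` (comma-separated flag names, `""` if
#'   none) and `verdict` (`pass` / `investigate` / `insufficient data`).
#' @export
evaluate_qc <- function(stats, rules = qc_ruleset()) {
  sd_rng <- rbind(child = rules$sd_range_child, wra = rules$sd_range_wra)
  one <- function(i) {
    s <- stats[i, ]
    vals <- c(sd = s$sd_gdl, skew = s$skewness_g1, kurt = s$kurtosis_g2,
              flag_pct = s$flag_pct)
    if (anyNA(vals)) {
      return(tibble::tibble(survey_id = s$survey_id, group = s$group,
                            sd_gdl = s$sd_gdl, skewness_g1 = s$skewness_g1,
                            kurtosis_g2 = s$kurtosis_g2,
                            flag_pct = s$flag_pct,
                            triggered = NA_character_,
                            verdict = "insufficient data"))
    }
    rng <- sd_rng[s$group, ]
    hit <- c(
      SKEW_HIGH = s$skewness_g1 > rules$skew_max,
      KURT_LOW = s$kurtosis_g2 < rules$kurt_min,
      SD_LOW = s$sd_gdl < rng[1],
      SD_HIGH = s$sd_gdl > rng[2],
      FLAG_PCT_HIGH = s$flag_pct > rules$flag_pct_max
    )
    tibble::tibble(
      survey_id = s$survey_id, group = s$group,
      sd_gdl = s$sd_gdl, skewness_g1 = s$skewness_g1,
      kurtosis_g2 = s$kurtosis_g2, flag_pct = s$flag_pct,
      triggered = paste(qc_flag_names[hit], collapse = ","),
      verdict = if (any(hit)) "investigate" else "pass"
    )
  }
  dplyr::bind_rows(lapply(seq_len(nrow(stats)), one))
}

#' Round to the nearest multiple of a step
#'
#' Ties round away from zero, so 1.525 with step 0.05 gives 1.55.
#'
#' @param x Numeric (vectorized).
#' @param step Positive step, default 0.05 g/dL.
#' @return `x` rounded to the nearest multiple of `step`.
#' @export
round_to_nearest <- function(x, step = 0.05) {
  stopifnot(step > 0)
  q <- abs(x) / step
  # guard binary representation of decimal inputs before the tie test
  q <- round(q, 9)
  f <- floor(q)
  up <- (q - f) >= 0.5
  sign(x) * (f + up) * step
}

#' Derive SD plausibility bounds from corpus percentiles
#'
#' The upper bound is the `p_high` quantile (default the 90th percentile) of
#' the survey-level SDs, rounded to the nearest `step`; the lower bound is
#' the `p_low` quantile (default the 2.5th), rounded likewise. An exclusion
#' predicate lets the caller drop subgroups suspected of quality problems
#' before deriving reference ranges.
#'
#' @param stats Per-survey statistics tibble ([summarize_surveys()] output)
#'   covering one or both groups.
#' @param p_low,p_high Quantile probabilities, defaults 0.025 and 0.90.
#' @param exclude Optional predicate `function(stats) logical` marking rows
#'   to drop (e.g. `function(s) s$country == "Uganda"`).
#' @param min_surveys Minimum surveys per group after exclusion, default 20.
#' @param step Rounding step in g/dL, default 0.05.
#' @param quantile_type Quantile definition id, default 7.
#' @return A tibble with one row per group: group, n_surveys, sd_p_low,
#'   sd_p_high (unrounded quantiles), lower, upper (rounded bounds); plus
#'   attribute `ruleset`, a [qc_ruleset()] carrying the derived SD ranges.
#' @export
derive_sd_thresholds <- function(stats, p_low = 0.025, p_high = 0.90,
                                 exclude = NULL, min_surveys = 20,
                                 step = 0.05, quantile_type = 7) {
  if (!is.null(exclude)) stats <- stats[!exclude(stats), , drop = FALSE]
  rows <- lapply(split(stats, stats$group), function(s) {
    if (nrow(s) < min_surveys) {
      stop("only ", nrow(s), " ", s$group[1], " survey(s) after exclusion; ",
           "need >= ", min_surveys, " to derive thresholds", call. = FALSE)
    }
    sds <- s$sd_gdl[!is.na(s$sd_gdl)]
    ql <- hb_quantile(sds, p_low, type = quantile_type)
    qh <- hb_quantile(sds, p_high, type = quantile_type)
    tibble::tibble(group = s$group[1], n_surveys = nrow(s),
                   sd_p_low = ql, sd_p_high = qh,
                   lower = round_to_nearest(ql, step),
                   upper = round_to_nearest(qh, step))
  })
  out <- dplyr::bind_rows(rows)
  rs <- qc_ruleset()
  for (g in out$group) {
    rng <- c(out$lower[out$group == g], out$upper[out$group == g])
    if (g == "child") rs$sd_range_child <- rng else rs$sd_range_wra <- rng
  }
  attr(out, "ruleset") <- rs
  out
}
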