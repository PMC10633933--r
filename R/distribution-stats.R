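#' Central sample moment
#'
#' \eqn{m_r = n^{-1} \sum_i (x_i - \bar x)^r}, the building block for the
#' bias-adjusted shape estimators.
#'
#' @param x Numeric vector, no missing values.
#' @param r Moment order (2, 3 or 4).
#' @return The r-th central moment, in (g/dL)^r for Hb input.
#' @export
central_moment <- function(x, r) {
  stopifnot(r %in% 2:4)
  if (length(x) == 0) stop("central moment undefined for empty input",
                           call. = FALSE)
  mean((x - mean(x))^r)
}

#' Sample standard deviation (n - 1 denominator)
#'
#' @param x Numeric vector.
#' @return SD in g/dL, or `NA` when fewer than two values.
#' @export
sample_sd <- function(x) {
  if (length(x) < 2) return(NA_real_)
  stats::sd(x)
}

#' Bias-adjusted sample skewness G1
#'
#' \eqn{g_1 = m_3 / m_2^{3/2}} adjusted as
#' \eqn{G_1 = g_1 \sqrt{n(n-1)} / (n-2)} (Joanes & Gill type 2).
#'
#' @param x Numeric vector.
#' @return Dimensionless skewness; `NA` when n < 3 or the sample is constant.
#' @export
skewness_g1 <- function(x) {
  n <- length(x)
  if (n < 3) return(NA_real_)
  m2 <- central_moment(x, 2)
  if (m2 == 0) return(NA_real_)
  g1 <- central_moment(x, 3) / m2^1.5
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

#' Bias-adjusted sample excess kurtosis G2
#'
#' \eqn{g_2 = m_4 / m_2^2 - 3} adjusted as
#' \eqn{G_2 = ((n+1) g_2 + 6)(n-1) / ((n-2)(n-3))} (Joanes & Gill type 2).
#' Centered at zero under normality.
#'
#' @param x Numeric vector.
#' @return Dimensionless excess kurtosis; `NA` when n < 4 or the sample is
#'   constant.
#' @export
kurtosis_g2 <- function(x) {
  n <- length(x)
  if (n < 4) return(NA_real_)
  m2 <- central_moment(x, 2)
  if (m2 == 0) return(NA_real_)
  g2 <- central_moment(x, 4) / m2^2 - 3
  ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3))
}

#' Order-statistic quantile
#'
#' Thin wrapper over [stats::quantile()] exposing the quantile-definition id
#' so reports can state which interpolation rule produced their percentiles.
#' For every definition p = 0 returns the minimum and p = 1 the maximum.
#'
#' @param x Numeric vector.
#' @param p Probability in \[0, 1\] (vectorized).
#' @param type Quantile definition id (1-9), default 7 (linear interpolation).
#' @return Quantile(s) in the units of `x`; `NA` for empty input.
#' @export
hb_quantile <- function(x, p, type = 7) {
  stopifnot(all(p >= 0 & p <= 1))
  if (length(x) == 0) return(rep(NA_real_, length(p)))
  unname(stats::quantile(x, probs = p, type = type, names = FALSE))
}

#' Summarize one survey's hemoglobin distribution
#'
#' Computes n, mean, median, SD, G1 skewness and G2 excess kurtosis and
#' anemia prevalence on the valid values inside the plausibility exclusion
#' range (default 4.0-18.0 g/dL). The flag percentage — the share of valid
#' values outside that range — is computed *before* the exclusion, on all
#' valid values.
#'
#' @param hb Numeric vector of valid Hb values (g/dL) for one survey group.
#' @param group `"child"` or `"wra"`.
#' @param survey_id Survey identifier carried into the output.
#' @param exclusion An [exclusion_policy()].
#' @param rules An [anemia_rules()].
#' @param quantile_type Quantile definition id for the median.
#' @return One-row tibble: survey_id, group, n, mean_gdl, median_gdl, sd_gdl,
#'   skewness_g1, kurtosis_g2, anemia_pct, flag_pct.
#' @export
summarize_survey <- function(hb, group, survey_id = NA_character_,
                             exclusion = exclusion_policy(),
                             rules = anemia_rules(), quantile_type = 7) {
  group <- match.arg(group, group_levels)
  hb <- hb[!is.na(hb)]
  n_all <- length(hb)
  ex <- apply_exclusion(hb, exclusion)
  kept <- ex$kept
  flag_pct <- if (n_all == 0) NA_real_ else
    100 * (ex$n_excluded_low + ex$n_excluded_high) / n_all
  if (length(kept) == 0) {
    return(tibble::tibble(
      survey_id = survey_id, group = group, n = 0L,
      mean_gdl = NA_real_, median_gdl = NA_real_, sd_gdl = NA_real_,
      skewness_g1 = NA_real_, kurtosis_g2 = NA_real_,
      anemia_pct = NA_real_, flag_pct = flag_pct
    ))
  }
  tibble::tibble(
    survey_id = survey_id, group = group, n = length(kept),
    mean_gdl = mean(kept),
    median_gdl = hb_quantile(kept, 0.5, type = quantile_type),
    sd_gdl = sample_sd(kept),
    skewness_g1 = skewness_g1(kept),
    kurtosis_g2 = kurtosis_g2(kept),
    anemia_pct = anemia_prevalence(kept, group, rules),
    flag_pct = flag_pct
  )
}

#' Per-survey statistics for a whole record corpus
#'
#' Maps [summarize_survey()] over every included survey-group combination of
#' a validity-marked record corpus, carrying country/site/year metadata.
#'
#' @param records A validity-marked records tibble (see [screen_surveys()]).
#' @param inclusion Optional inclusion tibble from [screen_surveys()]; only
#'   surveys with `include = TRUE` are summarized.
#' @inheritParams summarize_survey
#' @return A tibble with one row per survey group, ordered by survey_id.
#' @export
summarize_surveys <- function(records, inclusion = NULL,
                              exclusion = exclusion_policy(),
                              rules = anemia_rules(), quantile_type = 7) {
  stopifnot("hb_valid" %in% names(records))
  if (!is.null(inclusion)) {
    keep <- inclusion[inclusion$include, c("survey_id", "group")]
    records <- dplyr::semi_join(records, keep, by = c("survey_id", "group"))
  }
  valid <- records[records$hb_valid, , drop = FALSE]
  meta <- dplyr::summarise(
    dplyr::group_by(valid, .data$survey_id, .data$group),
    country = .data$country[1], site = .data$site[1], year = .data$year[1],
    .groups = "drop"
  )
  stats <- dplyr::group_modify(
    dplyr::group_by(valid, .data$survey_id, .data$group),
    function(d, key) {
      summarize_survey(d$hb_gdl, group = key$group, survey_id = key$survey_id,
                       exclusion = exclusion, rules = rules,
                       quantile_type = quantile_type)[, -(1:2)]
    }
  )
  out <- dplyr::left_join(dplyr::ungroup(stats), meta,
                          by = c("survey_id", "group"))
  dplyr::relocate(out, "country", "site", "year", .after = "group")
}
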