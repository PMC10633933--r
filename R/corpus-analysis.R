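#' Corpus-level summary of survey statistics
#'
#' For each per-survey statistic (mean, median, anemia prevalence, SD,
#' skewness, kurtosis) reports its mean and SD across surveys and the
#' quantiles min, P2.5, P10, P25, P50, P75, P90, P97.5, max. When an
#' exclusion predicate is given, both the full and the excluded variant are
#' returned, labelled.
#'
#' @param stats Per-survey statistics tibble ([summarize_surveys()] output).
#' @param group Optional group filter (`"child"` or `"wra"`).
#' @param exclude Optional predicate `function(stats) logical` marking rows
#'   to drop in the sensitivity variant.
#' @param exclude_label Label for the excluded variant, default
#'   `"excluded"`.
#' @param quantile_type Quantile definition id, default 7.
#' @return A tibble in long layout: group, variant, statistic, summary
#'   (mean/sd/min/p2.5/.../max), value.
#' @export
summarize_corpus <- function(stats, group = NULL, exclude = NULL,
                             exclude_label = "excluded", quantile_type = 7) {
  if (!is.null(group)) stats <- stats[stats$group == group, , drop = FALSE]
  variants <- list(all = stats)
  if (!is.null(exclude)) {
    variants[[exclude_label]] <- stats[!exclude(stats), , drop = FALSE]
  }
  stat_cols <- c(mean = "mean_gdl", median = "median_gdl",
                 anemia_pct = "anemia_pct", sd = "sd_gdl",
                 skewness = "skewness_g1", kurtosis = "kurtosis_g2")
  probs <- c(0, 0.025, 0.10, 0.25, 0.50, 0.75, 0.90, 0.975, 1)
  qlabs <- c("min", "p2.5", "p10", "p25", "p50", "p75", "p90", "p97.5", "max")
  out <- list()
  for (v in names(variants)) {
    sv <- variants[[v]]
    for (g in unique(sv$group)) {
      sg <- sv[sv$group == g, , drop = FALSE]
      if (nrow(sg) < 2) {
        stop("fewer than 2 surveys for group '", g, "' in variant '", v,
             "'", call. = FALSE)
      }
      for (nm in names(stat_cols)) {
        x <- sg[[stat_cols[nm]]]
        x <- x[!is.na(x)]
        out[[length(out) + 1]] <- tibble::tibble(
          group = g, variant = v, statistic = nm, n_surveys = nrow(sg),
          summary = c("mean", "sd", qlabs),
          value = c(mean(x), sample_sd(x),
                    hb_quantile(x, probs, type = quantile_type))
        )
      }
    }
  }
  dplyr::bind_rows(out)
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Rank correlation using mid-ranks for ties; the p-value comes from the
#' t approximation \eqn{t = \rho \sqrt{(n-2)/(1-\rho^2)}} on n - 2 degrees
#' of freedom (two-sided).
#'
#' @param x,y Numeric vectors of equal length, n >= 3; pairs with missing
#'   values are dropped.
#' @return List with `rho`, `p_value` and `n`.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    return(list(rho = NA_real_, p_value = NA_real_, n = n))
  }
  rho <- stats::cor(rx, ry)
  p <- if (abs(rho) >= 1) 0 else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tval), df = n - 2)
  }
  list(rho = rho, p_value = p, n = n)
}

#' Paired comparison of a survey-level statistic between children and WRA
#'
#' Matches surveys by `survey_id` across the two groups and compares the
#' chosen statistic with a paired test on the child - WRA differences:
#' two-sided t (default, reporting the 95% CI of the mean difference) or
#' Wilcoxon signed-rank.
#'
#' @param stats Per-survey statistics tibble containing both groups.
#' @param statistic Column to compare: `"sd_gdl"`, `"skewness_g1"` or
#'   `"kurtosis_g2"` (any numeric stats column works).
#' @param method `"t"` (default) or `"wilcoxon"`.
#' @return One-row tibble: statistic, n_pairs, mean_child, sd_child,
#'   mean_wra, sd_wra, difference (child - wra), ci_low, ci_high, p_value.
#'   For Wilcoxon the CI is the signed-rank pseudomedian interval.
#' @export
paired_compare <- function(stats, statistic = "sd_gdl",
                           method = c("t", "wilcoxon")) {
  method <- match.arg(method)
  stopifnot(statistic %in% names(stats))
  wide <- tidyr::pivot_wider(
    stats[, c("survey_id", "group", statistic)],
    names_from = "group", values_from = dplyr::all_of(statistic)
  )
  if (!all(c("child", "wra") %in% names(wide))) {
    stop("both groups must be present to pair surveys", call. = FALSE)
  }
  ok <- !is.na(wide$child) & !is.na(wide$wra)
  child <- wide$child[ok]; wra <- wide$wra[ok]
  n <- length(child)
  if (n < 2) stop("need at least 2 matched survey pairs", call. = FALSE)
  d <- child - wra
  if (stats::sd(d) < 1e-10 * max(abs(mean(d)), 1)) {
    warning("paired differences are constant; p-value unavailable",
            call. = FALSE)
    ci <- rep(mean(d), 2); p <- NA_real_
  } else if (method == "t") {
    tt <- stats::t.test(child, wra, paired = TRUE)
    ci <- as.numeric(tt$conf.int); p <- tt$p.value
  } else {
    wt <- stats::wilcox.test(child, wra, paired = TRUE, conf.int = TRUE,
                             exact = FALSE)
    ci <- as.numeric(wt$conf.int); p <- wt$p.value
  }
  tibble::tibble(
    statistic = statistic, n_pairs = n,
    mean_child = mean(child), sd_child = sample_sd(child),
    mean_wra = mean(wra), sd_wra = sample_sd(wra),
    difference = mean(d), ci_low = ci[1], ci_high = ci[2], p_value = p
  )
}

#' Survey-level mean-SD correlation
#'
#' Spearman correlation between per-survey mean Hb and SD, the diagnostic
#' for the tendency of high-anemia (low-mean) surveys to show wider Hb
#' dispersion.
#'
#' @param stats Per-survey statistics tibble (one group).
#' @param exclude Optional predicate marking rows to drop.
#' @return List with `rho`, `p_value` and `n` (see [spearman_rho()]).
#' @export
mean_sd_correlation <- function(stats, exclude = NULL) {
  if (!is.null(exclude)) stats <- stats[!exclude(stats), , drop = FALSE]
  spearman_rho(stats$mean_gdl, stats$sd_gdl)
}
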