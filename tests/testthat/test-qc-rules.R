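stats_row <- function(sd = 1.34, skew = -0.38, kurt = 0.55, flag = 0.08,
                      group = "child", id = "s1") {
  tibble::tibble(survey_id = id, group = group, n = 400L,
                 mean_gdl = 11.1, median_gdl = 11.2, sd_gdl = sd,
                 skewness_g1 = skew, kurtosis_g2 = kurt,
                 anemia_pct = 43.5, flag_pct = flag)
}

test_that("a typical field survey passes all rules", {
  rep <- evaluate_qc(stats_row())
  expect_equal(rep$verdict, "pass")
  expect_equal(rep$triggered, "")
})

test_that("each rule triggers its own flag", {
  expect_equal(evaluate_qc(stats_row(sd = 1.70, group = "wra"))$triggered,
               "SD_HIGH")
  expect_equal(evaluate_qc(stats_row(sd = 1.05))$triggered, "SD_LOW")
  rep <- evaluate_qc(stats_row(skew = 0.25, kurt = -0.6, flag = 1.2))
  expect_equal(rep$triggered, "SKEW_HIGH,KURT_LOW,FLAG_PCT_HIGH")
  expect_equal(rep$verdict, "investigate")
})

test_that("boundary statistics pass (strict comparisons)", {
  expect_equal(evaluate_qc(stats_row(sd = 1.55))$verdict, "pass")
  expect_equal(evaluate_qc(stats_row(sd = 1.65, group = "wra"))$verdict,
               "pass")
  expect_equal(evaluate_qc(stats_row(sd = 1.10))$verdict, "pass")
  expect_equal(evaluate_qc(stats_row(skew = 0.2))$verdict, "pass")
  expect_equal(evaluate_qc(stats_row(kurt = -0.5))$verdict, "pass")
  expect_equal(evaluate_qc(stats_row(flag = 1.0))$verdict, "pass")
})

test_that("incomplete statistics yield an insufficient-data verdict", {
  s <- stats_row(); s$kurtosis_g2 <- NA_real_
  expect_equal(evaluate_qc(s)$verdict, "insufficient data")
})

test_that("passing surveys still pass under any more lenient rule set", {
  set.seed(17)
  base <- qc_ruleset()
  for (i in 1:100) {
    s <- stats_row(sd = runif(1, 0.9, 1.9), skew = runif(1, -1, 0.5),
                   kurt = runif(1, -1, 2), flag = runif(1, 0, 2))
    lenient <- qc_ruleset(
      skew_max = base$skew_max + runif(1, 0, 0.3),
      kurt_min = base$kurt_min - runif(1, 0, 0.3),
      sd_range_child = base$sd_range_child + c(-1, 1) * runif(1, 0, 0.2),
      sd_range_wra = base$sd_range_wra + c(-1, 1) * runif(1, 0, 0.2),
      flag_pct_max = base$flag_pct_max + runif(1, 0, 1)
    )
    if (evaluate_qc(s, base)$verdict == "pass") {
      expect_equal(evaluate_qc(s, lenient)$verdict, "pass")
    }
  }
})

test_that("rounding to 0.05 reproduces the proposed SD bounds", {
  expect_equal(round_to_nearest(1.53), 1.55)
  expect_equal(round_to_nearest(1.66), 1.65)
  expect_equal(round_to_nearest(1.525), 1.55)   # tie away from zero
  expect_equal(round_to_nearest(-1.525), -1.55)
})

test_that("round_to_nearest is idempotent and within half a step", {
  set.seed(4)
  x <- runif(200, -3, 3)
  r <- round_to_nearest(x)
  expect_equal(round_to_nearest(r), r)
  expect_true(all(abs(r - x) <= 0.025 + 1e-12))
})

test_that("threshold derivation rounds corpus percentiles per group", {
  set.seed(9)
  mk <- function(g, sds) dplyr::bind_rows(lapply(seq_along(sds), function(i)
    stats_row(sd = sds[i], group = g, id = sprintf("%s%03d", g, i))))
  # 21 surveys whose P90 (type 7) lands exactly on the 19th order
  # statistic, set to 1.53
  sds <- c(seq(1.1, 1.53, length.out = 19), 1.6, 1.7)
  stats <- mk("child", sds)
  expect_equal(unname(stats::quantile(sds, 0.9, type = 7)), 1.53)
  th <- derive_sd_thresholds(stats)
  expect_equal(th$upper, 1.55)
  # degenerate corpus: both bounds collapse to the rounded common SD
  th2 <- derive_sd_thresholds(mk("wra", rep(1.42, 25)))
  expect_equal(th2$lower, 1.40)
  expect_equal(th2$upper, 1.40)
  expect_error(derive_sd_thresholds(mk("child", rep(1.3, 5))), "need >= 20")
})

test_that("derived thresholds recover a known SD hyper-distribution P90", {
  cs <- corpus_spec(n_surveys = 150, seed = 77)
  corp <- generate_corpus(cs)
  scr <- screen_surveys(corp$records)
  stats <- summarize_surveys(scr$records, scr$inclusion)
  th <- derive_sd_thresholds(stats)
  # child hyper N(1.39, 0.21): P90 = 1.39 + 1.2816*0.21 = 1.659
  expect_equal(th$sd_p_high[th$group == "child"], 1.659, tolerance = 0.06)
})
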