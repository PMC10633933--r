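#!/usr/bin/env Rscript
# Screen the corpus (dedupe, validity, 30% rule) and characterize every
# survey's Hb distribution: n, mean, median, SD, G1 skewness, G2 excess
# kurtosis, anemia prevalence, flag percentage.

library(hbqc)

rec <- read_hb_records("results/corpus/corpus.csv")
scr <- screen_surveys(rec)
cat("surveys screened:", nrow(scr$inclusion),
    "included:", sum(scr$inclusion$include), "\n")

stats <- summarize_surveys(scr$records, scr$inclusion)
readr::write_csv(stats, "results/survey_stats.csv")

for (g in c("child", "wra")) {
  s <- stats[stats$group == g, ]
  cat(sprintf(
    "%5s surveys: n=%d  mean Hb %.2f  mean SD %.3f  mean G1 %+.3f  mean G2 %+.3f  mean anemia %.1f%%\n",
    g, nrow(s), mean(s$mean_gdl), mean(s$sd_gdl), mean(s$skewness_g1),
    mean(s$kurtosis_g2), mean(s$anemia_pct)))
}
cat("per-survey statistics written to results/survey_stats.csv\n")
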