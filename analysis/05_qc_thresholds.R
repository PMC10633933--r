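#!/usr/bin/env Rscript
# Derive SD plausibility bounds from the corpus percentiles (P2.5 lower,
# P90 upper, rounded to the nearest 0.05 g/dL) and evaluate every survey
# against the full QC rule set, writing per-survey verdicts.

library(hbqc)

stats <- readr::read_csv("results/survey_stats.csv", show_col_types = FALSE)

th <- derive_sd_thresholds(stats)
readr::write_csv(th, "results/derived_sd_thresholds.csv")
cat("derived SD bounds (P2.5 / P90, rounded to 0.05):\n")
print(as.data.frame(th), row.names = FALSE, digits = 4)

reports <- evaluate_qc(stats)
readr::write_csv(reports, "results/qc_reports.csv")
n_inv <- sum(reports$verdict == "investigate")
cat(sprintf("\n%d of %d surveys flagged for quality investigation (%.1f%%)\n",
            n_inv, nrow(reports), 100 * n_inv / nrow(reports)))
print(table(unlist(strsplit(reports$triggered[reports$triggered != ""],
                            ","))))
cat("per-survey QC verdicts written to results/qc_reports.csv\n")
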