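#!/usr/bin/env Rscript
# Tabulate implausible Hb values across exclusion cutoffs (below 4/5/6,
# above 16/17/18 g/dL, and the combined 4.0-18.0 flagging range), at record
# and survey level, for each demographic group.

library(hbqc)

rec <- mark_validity(read_hb_records("results/corpus/corpus.csv"))
for (g in c("child", "wra")) {
  tab <- tabulate_flags(rec, group = g)
  readr::write_csv(tab, sprintf("results/flags_%s.csv", g))
  comb <- tab[grepl(" or ", tab$cutoff_label), ]
  cat(sprintf(
    "%5s: %.3f%% of %d records outside 4.0-18.0; %.1f%% of %d surveys have >1%% flags\n",
    g, comb$record_pct, comb$n_records[1], comb$surveys_gt1_pct,
    comb$n_surveys[1]))
}
cat("flag tables written to results/flags_{child,wra}.csv\n")
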