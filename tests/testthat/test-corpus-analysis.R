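mk_stats <- function(g, sds, means = NULL, ids = NULL) {
  k <- length(sds)
  ids <- ids %||% sprintf("s%03d", seq_len(k))
  means <- means %||% rep(11.1, k)
  tibble::tibble(
    survey_id = ids, group = g, n = 300L,
    mean_gdl = means, median_gdl = 11.2, sd_gdl = sds,
    skewness_g1 = -0.38, kurtosis_g2 = 0.55, anemia_pct = 40,
    flag_pct = 0.1
  )
}

test_that("corpus summary reports mean/min/max across surveys", {
  st <- mk_stats("child", c(1.2, 1.3, 1.4))
  cs <- summarize_corpus(st)
  sdrows <- cs[cs$statistic == "sd", ]
  expect_equal(sdrows$value[sdrows$summary == "mean"], 1.3)
  expect_equal(sdrows$value[sdrows$summary == "min"], 1.2)
  expect_equal(sdrows$value[sdrows$summary == "max"], 1.4)
})

test_that("an exclusion filter matching nothing reproduces the full corpus", {
  st <- mk_stats("child", seq(1.1, 1.6, by = 0.05))
  st$country <- "A"
  cs <- summarize_corpus(st, exclude = function(s) s$country == "Nowhere",
                         exclude_label = "noUganda")
  full <- cs[cs$variant == "all", c("statistic", "summary", "value")]
  excl <- cs[cs$variant == "noUganda", c("statistic", "summary", "value")]
  expect_equal(full, excl)
})

test_that("corpus quantile rows are monotone nondecreasing", {
  cs_spec <- corpus_spec(n_surveys = 25, seed = 41)
  scr <- screen_surveys(generate_corpus(cs_spec)$records)
  stats <- summarize_surveys(scr$records, scr$inclusion)
  cs <- summarize_corpus(stats)
  qlabs <- c("min", "p2.5", "p10", "p25", "p50", "p75", "p90", "p97.5",
             "max")
  for (g in unique(cs$group)) for (stt in unique(cs$statistic)) {
    v <- cs[cs$group == g & cs$statistic == stt, ]
    q <- v$value[match(qlabs, v$summary)]
    expect_true(all(diff(q) >= 0))
  }
})

test_that("spearman_rho handles monotone, tied, and transformed input", {
  x <- 1:10
  expect_equal(spearman_rho(x, 2 * x + 3)$rho, 1)
  expect_equal(spearman_rho(x, -x)$rho, -1)
  # tied fixture against the reference rank-correlation implementation
  a <- c(1, 2, 2, 3); b <- c(1, 3, 2, 4)
  expect_equal(spearman_rho(a, b)$rho,
               unname(cor(a, b, method = "spearman")))
  # invariance under strictly monotone transforms
  set.seed(6)
  u <- runif(30); v <- runif(30)
  expect_equal(spearman_rho(u, v)$rho, spearman_rho(exp(u), v^3)$rho)
  expect_equal(spearman_rho(u, v)$rho, spearman_rho(v, u)$rho)
  expect_true(is.na(spearman_rho(rep(1, 5), 1:5)$rho))
})

test_that("spearman p-value matches the t approximation", {
  set.seed(12)
  x <- rnorm(40); y <- x + rnorm(40, sd = 2)
  r <- spearman_rho(x, y)
  tval <- r$rho * sqrt((40 - 2) / (1 - r$rho^2))
  expect_equal(r$p_value, 2 * pt(-abs(tval), 38))
  expect_true(r$rho >= -1 && r$rho <= 1)
})

test_that("paired comparison fixes the child-minus-wra sign convention", {
  st <- dplyr::bind_rows(
    mk_stats("child", c(1.3, 1.4, 1.5), ids = c("a", "b", "c")),
    mk_stats("wra", c(1.4, 1.5, 1.6), ids = c("a", "b", "c"))
  )
  expect_warning(pc <- paired_compare(st, "sd_gdl"), "constant")
  expect_equal(pc$difference, -0.1)
  expect_equal(c(pc$ci_low, pc$ci_high), c(-0.1, -0.1))
  # identical vectors: zero difference, degenerate CI
  st2 <- dplyr::bind_rows(
    mk_stats("child", c(1.3, 1.4), ids = c("a", "b")),
    mk_stats("wra", c(1.3, 1.4), ids = c("a", "b"))
  )
  expect_warning(pc2 <- paired_compare(st2, "sd_gdl"))
  expect_equal(pc2$difference, 0)
})

test_that("paired CI covers a built-in SD gap in seeded replicates", {
  hit <- 0; reps <- 60
  for (r in seq_len(reps)) {
    set.seed(1000 + r)
    n <- 40
    base <- rnorm(n, 1.39, 0.15)
    child <- base + rnorm(n, 0, 0.05)
    wra <- base + 0.07 + rnorm(n, 0, 0.05)
    st <- dplyr::bind_rows(
      mk_stats("child", child, ids = sprintf("p%02d", 1:n)),
      mk_stats("wra", wra, ids = sprintf("p%02d", 1:n))
    )
    pc <- paired_compare(st, "sd_gdl")
    if (pc$ci_low <= -0.07 && -0.07 <= pc$ci_high) hit <- hit + 1
  }
  expect_gte(hit / reps, 0.9)
})

test_that("mean-SD correlation detects coupling and respects the null", {
  means <- seq(10, 13, length.out = 30)
  st <- mk_stats("child", sds = rev(seq(1.1, 1.7, length.out = 30)),
                 means = means)
  r <- mean_sd_correlation(st)
  expect_equal(r$rho, -1)
  set.seed(55)
  st2 <- mk_stats("child", sds = runif(200, 1.1, 1.7),
                  means = runif(200, 10, 13))
  r2 <- mean_sd_correlation(st2)
  expect_lt(abs(r2$rho), 0.2)
  expect_gt(r2$p_value, 0.01)
})

test_that("generator mean-SD coupling propagates to a negative rho", {
  cs <- corpus_spec(n_surveys = 120, seed = 61)
  scr <- screen_surveys(generate_corpus(cs)$records)
  stats <- summarize_surveys(scr$records, scr$inclusion)
  r <- mean_sd_correlation(stats[stats$group == "child", ])
  expect_lt(r$rho, 0)
})
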