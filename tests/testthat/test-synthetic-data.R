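test_that("zero shape targets give the identity transform", {
  cf <- fleishman_coefficients(0, 0)
  expect_equal(unname(cf), c(0, 1, 0, 0), tolerance = 1e-9)
})

test_that("solved coefficients reproduce their targets by quadrature", {
  targets <- list(c(-0.53, 1.15), c(-0.37, 0.54), c(0.8, 1.0), c(0, -1.0))
  for (tg in targets) {
    cf <- fleishman_coefficients(tg[1], tg[2])
    m1 <- oracle_fleishman_moment(cf, 1)
    m2 <- oracle_fleishman_moment(cf, 2) - m1^2
    m3 <- oracle_fleishman_moment(cf, 3) - 3 * m1 * (m2 + m1^2) + 2 * m1^3
    expect_equal(m1, 0, tolerance = 1e-8)
    expect_equal(m2, 1, tolerance = 1e-8)
    expect_equal(m3 / m2^1.5, tg[1], tolerance = 1e-7)
    # package's own symbolic moments must agree too
    mm <- fleishman_moments(cf)
    expect_equal(mm$skew, tg[1], tolerance = 1e-9)
    expect_equal(mm$exkurt, tg[2], tolerance = 1e-9)
  }
})

test_that("infeasible moment targets raise an explicit boundary error", {
  expect_error(fleishman_coefficients(2, -1), "infeasible")
  expect_error(fleishman_coefficients(2, -1), "5.33")
})

test_that("survey generation is deterministic under a fixed seed", {
  sp <- survey_spec(n = 500, seed = 123)
  expect_identical(generate_survey(sp), generate_survey(sp))
  sp2 <- survey_spec(n = 500, seed = 124)
  expect_false(identical(generate_survey(sp)$hb_gdl,
                         generate_survey(sp2)$hb_gdl))
})

test_that("corpus CSV output is byte-identical across runs", {
  cs <- corpus_spec(n_surveys = 4, seed = 5)
  d1 <- tempfile(); d2 <- tempfile()
  run_simulation(cs, d1)
  run_simulation(cs, d2)
  expect_identical(readLines(file.path(d1, "corpus.csv")),
                   readLines(file.path(d2, "corpus.csv")))
})

test_that("contamination injects the configured share of gross errors", {
  sp <- survey_spec(n = 1e5, contamination_rate = 0.01, seed = 9)
  rec <- generate_survey(sp)
  frac <- mean(rec$hb_gdl < 4 | rec$hb_gdl > 18)
  se <- sqrt(0.01 * 0.99 / 1e5)
  expect_lt(abs(frac - 0.01), 3 * se + 2e-4)
})

test_that("without contamination the tail mass beyond 4-18 stays tiny", {
  sp <- survey_spec(n = 1e5, seed = 10)  # child defaults
  rec <- generate_survey(sp)
  expect_lt(100 * mean(rec$hb_gdl < 4 | rec$hb_gdl > 18), 0.5)
})

test_that("parameter recovery bias shrinks with sample size", {
  err <- vapply(c(400, 1e4, 1e6), function(n) {
    sp <- survey_spec(n = n, seed = 44)
    x <- generate_survey(sp)$hb_gdl
    abs(mean(x) - 11.1) + abs(sample_sd(x) - 1.39)
  }, numeric(1))
  expect_lt(err[3], err[1])
  expect_lt(err[3], 0.01)
})

test_that("generated values honour device rounding and validity range", {
  sp <- survey_spec(n = 2000, contamination_rate = 0.05, seed = 2)
  hb <- generate_survey(sp)$hb_gdl
  expect_true(all(hb >= 0 & hb <= 25.6))
  expect_equal(hb, round_to_nearest(hb, 0.1))
})

test_that("zero hyper-spread corpora share identical targets", {
  hyper0 <- list(
    child = list(mean = c(11.1, 0), sd = c(1.39, 0), skew = c(-0.37, 0),
                 exkurt = c(0.54, 0)),
    wra = list(mean = c(12.6, 0), sd = c(1.47, 0), skew = c(-0.53, 0),
               exkurt = c(1.15, 0))
  )
  cs <- corpus_spec(n_surveys = 6, hyper = hyper0, seed = 14)
  tg <- generate_corpus(cs)$targets
  expect_equal(unique(tg$target_sd[tg$group == "child"]), 1.39)
  expect_equal(unique(tg$target_mean[tg$group == "wra"]), 12.6)
})

test_that("corpus round-trips through the CSV reader unchanged", {
  cs <- corpus_spec(n_surveys = 3, seed = 8)
  corp <- generate_corpus(cs)
  path <- write_records_csv(corp$records)
  back <- read_hb_records(path)
  expect_equal(back$hb_gdl, corp$records$hb_gdl)
  expect_equal(back$survey_id, corp$records$survey_id)
  expect_equal(nrow(back), nrow(corp$records))
})
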