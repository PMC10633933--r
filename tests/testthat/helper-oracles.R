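# Independent brute-force oracles, kept deliberately separate from the
# package implementations they check.

# Joanes-Gill bias-adjusted skewness, coded directly from the definition
oracle_g1 <- function(x) {
  n <- length(x)
  xb <- sum(x) / n
  m2 <- sum((x - xb)^2) / n
  m3 <- sum((x - xb)^3) / n
  b1 <- m3 / m2^(3 / 2)
  sqrt(n * (n - 1)) / (n - 2) * b1
}

# Joanes-Gill bias-adjusted excess kurtosis
oracle_g2 <- function(x) {
  n <- length(x)
  xb <- sum(x) / n
  m2 <- sum((x - xb)^2) / n
  m4 <- sum((x - xb)^4) / n
  b2 <- m4 / m2^2
  (n - 1) / ((n - 2) * (n - 3)) * ((n + 1) * (b2 - 3) + 6)
}

# Moments of a + bZ + cZ^2 + dZ^3 by adaptive quadrature over the normal
# density -- a route independent of the package's polynomial expansion
oracle_fleishman_moment <- function(coef, r) {
  f <- function(z) {
    x <- coef["a"] + coef["b"] * z + coef["c"] * z^2 + coef["d"] * z^3
    x^r * stats::dnorm(z)
  }
  stats::integrate(f, -10, 10, rel.tol = 1e-12, abs.tol = 1e-12)$value
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small records tibble builder for ingestion/flagging tests
make_records <- function(hb, survey_id = "s1", group = "child",
                         country = "A", site = "x", year = 2021L) {
  n <- length(hb)
  tibble::tibble(
    record_id = sprintf("r%04d", seq_len(n)),
    survey_id = rep_len(survey_id, n),
    country = rep_len(country, n), site = rep_len(site, n),
    year = rep_len(year, n), group = rep_len(group, n),
    hb_gdl = hb, altitude_m = NA_real_, pregnant = FALSE,
    altitude_adjusted = TRUE
  )
}

write_records_csv <- function(records, path = tempfile(fileext = ".csv")) {
  readr::write_csv(records, path)
  path
}
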