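#' Fleishman feasibility boundary
#'
#' The third-order polynomial transform of a standard normal can only reach
#' (skewness, excess kurtosis) pairs above a boundary curve, commonly
#' approximated by \eqn{\gamma_2 \ge -1.2264489 + 1.6410373\,\gamma_1^2}.
#' The approximation is a lower envelope: targets below it are certainly
#' infeasible, while the family's true boundary sits up to about 0.08
#' higher (e.g. -1.1513 at zero skewness).
#'
#' @param skew Target skewness.
#' @return Approximate minimum achievable excess kurtosis at that skewness.
#' @export
fleishman_kurtosis_floor <- function(skew) {
  -1.2264489 + 1.6410373 * skew^2
}

#' Solve Fleishman polynomial coefficients for target moments
#'
#' Finds (a, b, c, d) with a = -c such that X = a + bZ + cZ^2 + dZ^3
#' (Z standard normal) has mean 0, variance 1 and the requested third and
#' fourth standardized moments. Solved by damped Newton iteration on the
#' three moment equations to residual < 1e-9.
#'
#' @param skew Target skewness (third standardized moment).
#' @param exkurt Target excess kurtosis (fourth standardized moment - 3).
#' @return Named numeric vector `c(a, b, c, d)`.
#' @export
fleishman_coefficients <- function(skew, exkurt) {
  floor_k <- fleishman_kurtosis_floor(skew)
  if (exkurt < floor_k) {
    stop(sprintf(paste0(
      "targets (skew = %.4g, excess kurtosis = %.4g) are infeasible for ",
      "the Fleishman family: excess kurtosis must be >= %.4f at this ",
      "skewness"), skew, exkurt, floor_k), call. = FALSE)
  }
  fn <- function(p) {
    b <- p[1]; cc <- p[2]; d <- p[3]
    c(b^2 + 6 * b * d + 2 * cc^2 + 15 * d^2 - 1,
      2 * cc * (b^2 + 24 * b * d + 105 * d^2 + 2) - skew,
      24 * (b * d + cc^2 * (1 + b^2 + 28 * b * d) +
              d^2 * (12 + 48 * b * d + 141 * cc^2 + 225 * d^2)) - exkurt)
  }
  jac <- function(p) {
    b <- p[1]; cc <- p[2]; d <- p[3]
    rbind(
      c(2 * b + 6 * d, 4 * cc, 6 * b + 30 * d),
      c(4 * cc * (b + 12 * d),
        2 * (b^2 + 24 * b * d + 105 * d^2 + 2),
        2 * cc * (24 * b + 210 * d)),
      24 * c(d + 2 * b * cc^2 + 28 * d * cc^2 + 48 * d^3,
             2 * cc + 2 * b^2 * cc + 56 * b * d * cc + 282 * cc * d^2,
             b + 28 * b * cc^2 + 24 * d + 144 * b * d^2 +
               282 * cc^2 * d + 900 * d^3)
    )
  }
  solve_at <- function(k2, starts) {
    fnk <- function(p) {
      b <- p[1]; cc <- p[2]; d <- p[3]
      c(b^2 + 6 * b * d + 2 * cc^2 + 15 * d^2 - 1,
        2 * cc * (b^2 + 24 * b * d + 105 * d^2 + 2) - skew,
        24 * (b * d + cc^2 * (1 + b^2 + 28 * b * d) +
                d^2 * (12 + 48 * b * d + 141 * cc^2 + 225 * d^2)) - k2)
    }
    for (p in starts) {
      sol <- newton_system(fnk, jac, p)
      if (!is.null(sol)) return(sol)
    }
    NULL
  }
  starts <- list(c(1, skew / 6, exkurt / 24),
                 c(0.9, skew / 5, 0.05),
                 c(1, 0.01 * sign(skew + 1e-12), 0),
                 c(0.8, skew / 4, 0.1))
  sol <- solve_at(exkurt, starts)
  if (is.null(sol)) {
    # near the feasibility boundary Newton needs a warm start: walk the
    # kurtosis down from an easy interior target with adaptive steps,
    # reusing each solution as the next start
    k_easy <- max(exkurt + 2, floor_k + 2)
    sol <- solve_at(k_easy, starts)
    if (!is.null(sol)) {
      k_cur <- k_easy
      step <- (k_easy - exkurt) / 20
      while (k_cur > exkurt && !is.null(sol) && step > 1e-7) {
        k_next <- max(exkurt, k_cur - step)
        sol_next <- solve_at(k_next, list(sol))
        if (is.null(sol_next)) {
          step <- step / 2
        } else {
          sol <- sol_next
          k_cur <- k_next
          step <- step * 1.5
        }
      }
      if (k_cur > exkurt) sol <- NULL
    }
  }
  if (!is.null(sol)) {
    b <- sol[1]; cc <- sol[2]; d <- sol[3]
    return(c(a = -cc, b = b, c = cc, d = d))
  }
  stop("Fleishman coefficient solve failed to converge for targets (",
       skew, ", ", exkurt, ")", call. = FALSE)
}

# damped Newton for a small square system; returns NULL on failure
newton_system <- function(fn, jac, p, tol = 1e-12, maxit = 400) {
  f <- fn(p)
  for (it in seq_len(maxit)) {
    if (max(abs(f)) < tol) return(p)
    step <- tryCatch(solve(jac(p), f), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    lambda <- 1
    repeat {
      p_new <- p - lambda * step
      f_new <- fn(p_new)
      if (all(is.finite(f_new)) && sum(f_new^2) < sum(f^2)) break
      lambda <- lambda / 2
      if (lambda < 1e-12) {
        return(if (max(abs(f)) < 1e-9) p else NULL)
      }
    }
    p <- p_new; f <- f_new
  }
  if (max(abs(f)) < 1e-9) p else NULL
}

#' Population moments of a Fleishman polynomial transform
#'
#' Expands X = a + bZ + cZ^2 + dZ^3 in powers of Z and evaluates the first
#' four moments exactly from the normal moments E[Z^k] (zero for odd k,
#' (k-1)!! for even k). Used to verify solved coefficients.
#'
#' @param coef Named vector `c(a, b, c, d)`.
#' @return List with `mean`, `var`, `skew`, `exkurt`.
#' @export
fleishman_moments <- function(coef) {
  # coefficient vector over Z^0..Z^3; powers via repeated convolution
  p1 <- unname(coef[c("a", "b", "c", "d")])
  ez <- function(k) if (k %% 2 == 1) 0 else prod(seq(1, max(k - 1, 1), by = 2))
  mom_raw <- function(pv) sum(pv * vapply(seq_along(pv) - 1, ez, numeric(1)))
  pk <- p1
  raw <- numeric(4)
  for (r in 1:4) {
    raw[r] <- mom_raw(pk)
    if (r < 4) pk <- stats::convolve(pk, rev(p1), type = "open")
  }
  mu <- raw[1]
  v <- raw[2] - mu^2
  m3 <- raw[3] - 3 * mu * raw[2] + 2 * mu^3
  m4 <- raw[4] - 4 * mu * raw[3] + 6 * mu^2 * raw[2] - 3 * mu^4
  list(mean = mu, var = v, skew = m3 / v^1.5, exkurt = m4 / v^2 - 3)
}

#' Specification of one synthetic survey
#'
#' Target moments for the generated Hb distribution plus gross-error
#' contamination. Defaults are the corpus-average child survey: mean 11.1,
#' SD 1.39 g/dL, skewness -0.37, excess kurtosis 0.54, n 400, no
#' contamination. Values are rounded to the 0.1 g/dL display precision of a
#' field photometer and clipped to its 0-25.6 g/dL reporting range.
#'
#' @param n Sample size.
#' @param target_mean,target_sd Mean and SD in g/dL.
#' @param target_skew,target_exkurt Standardized shape targets.
#' @param contamination_rate Probability a record is replaced by a gross
#'   error, in \[0, 0.1\].
#' @param contamination_low,contamination_high Ranges (g/dL) the gross
#'   errors are drawn from uniformly, half low, half high.
#' @param rounding_step Display precision in g/dL (0 disables rounding).
#' @param seed Integer seed.
#' @param survey_id,group,country,site,year Metadata carried into records.
#' @return A list of class `survey_spec`.
#' @export
survey_spec <- function(n = 400, target_mean = 11.1, target_sd = 1.39,
                        target_skew = -0.37, target_exkurt = 0.54,
                        contamination_rate = 0,
                        contamination_low = c(1.0, 4.0),
                        contamination_high = c(18.0, 25.6),
                        rounding_step = 0.1, seed = 1L,
                        survey_id = "s001", group = "child",
                        country = "Synthetica", site = "site1", year = 2021L) {
  stopifnot(n >= 1, target_sd > 0,
            contamination_rate >= 0, contamination_rate <= 0.1)
  structure(list(
    n = n, target_mean = target_mean, target_sd = target_sd,
    target_skew = target_skew, target_exkurt = target_exkurt,
    contamination_rate = contamination_rate,
    contamination_low = contamination_low,
    contamination_high = contamination_high,
    rounding_step = rounding_step, seed = as.integer(seed),
    survey_id = survey_id, group = group, country = country, site = site,
    year = year
  ), class = "survey_spec")
}

#' Generate one synthetic survey
#'
#' Draws n values through the Fleishman transform matching the spec's
#' moments, rescales to the target mean and SD, injects gross-error
#' contamination, rounds to the display step and clips to the analyzer
#' validity range. Fully reproducible from the spec's seed.
#'
#' @param spec A [survey_spec()].
#' @return A records tibble in the same schema [read_hb_records()] returns.
#' @export
generate_survey <- function(spec) {
  cf <- fleishman_coefficients(spec$target_skew, spec$target_exkurt)
  set.seed(spec$seed)
  z <- stats::rnorm(spec$n)
  x <- cf["a"] + cf["b"] * z + cf["c"] * z^2 + cf["d"] * z^3
  hb <- spec$target_mean + spec$target_sd * x
  if (spec$contamination_rate > 0) {
    bad <- stats::runif(spec$n) < spec$contamination_rate
    if (any(bad)) {
      nb <- sum(bad)
      side_low <- stats::runif(nb) < 0.5
      lo <- stats::runif(nb, spec$contamination_low[1],
                         spec$contamination_low[2])
      hi <- stats::runif(nb, spec$contamination_high[1],
                         spec$contamination_high[2])
      hb[bad] <- ifelse(side_low, lo, hi)
    }
  }
  if (spec$rounding_step > 0) {
    hb <- round_to_nearest(hb, spec$rounding_step)
  }
  hb <- pmin(pmax(hb, 0), 25.6)
  tibble::tibble(
    record_id = sprintf("%s-%s-%06d", spec$survey_id, spec$group,
                        seq_len(spec$n)),
    survey_id = spec$survey_id,
    country = spec$country, site = spec$site, year = spec$year,
    group = spec$group, hb_gdl = hb,
    altitude_m = NA_real_, pregnant = FALSE, altitude_adjusted = TRUE
  )
}

#' Specification of a synthetic multi-survey corpus
#'
#' Each site contributes a paired child and WRA survey. Per-survey moment
#' targets are drawn from normal hyper-distributions whose defaults match
#' the across-survey mean and SD observed in a large refugee-setting corpus:
#' child mean 11.1 (0.50), SD 1.39 (0.21), skewness -0.37 (0.26), excess
#' kurtosis 0.54 (0.67); WRA mean 12.6 (0.57), SD 1.47 (0.23), skewness
#' -0.53 (0.36), excess kurtosis 1.15 (1.17). Latent mean-SD coupling
#' defaults to rho -0.33 (child) and -0.15 (WRA), and the child/WRA SD
#' targets of a site are correlated at rho 0.52; kurtosis draws below the
#' Fleishman feasibility floor are lifted onto it.
#'
#' @param n_surveys Number of sites (each with a child and a WRA survey),
#'   default 379.
#' @param hyper Named list of `c(mean, sd)` hyper-parameters per group and
#'   target; see default for structure.
#' @param mean_sd_rho Latent correlation between a survey's mean and SD
#'   targets, named per group.
#' @param sd_cross_rho Latent correlation between child and WRA SD targets
#'   at the same site.
#' @param n_range Per-survey sample-size ranges (uniform draw), named per
#'   group; defaults span the central 90% of observed field sample sizes.
#' @param contamination_rate Shared gross-error rate for all surveys.
#' @param rounding_step Display precision in g/dL.
#' @param seed Master seed; per-survey seeds derive from it.
#' @return A list of class `corpus_spec`.
#' @export
corpus_spec <- function(n_surveys = 379,
                        hyper = list(
                          child = list(mean = c(11.1, 0.50),
                                       sd = c(1.39, 0.21),
                                       skew = c(-0.37, 0.26),
                                       exkurt = c(0.54, 0.67)),
                          wra = list(mean = c(12.6, 0.57),
                                     sd = c(1.47, 0.23),
                                     skew = c(-0.53, 0.36),
                                     exkurt = c(1.15, 1.17))),
                        mean_sd_rho = c(child = -0.33, wra = -0.15),
                        sd_cross_rho = 0.52,
                        n_range = list(child = c(175, 649),
                                       wra = c(99, 406)),
                        contamination_rate = 0,
                        rounding_step = 0.1, seed = 1L) {
  stopifnot(n_surveys >= 1,
            all(vapply(hyper, function(g)
              all(vapply(g, function(v) v[2] >= 0, logical(1))),
              logical(1))))
  structure(list(n_surveys = n_surveys, hyper = hyper,
                 mean_sd_rho = mean_sd_rho, sd_cross_rho = sd_cross_rho,
                 n_range = n_range, contamination_rate = contamination_rate,
                 rounding_step = rounding_step, seed = as.integer(seed)),
            class = "corpus_spec")
}

#' Generate a paired synthetic survey corpus
#'
#' Draws per-site latent (mean, SD) targets for both groups from a
#' multivariate normal encoding the mean-SD coupling and the cross-group SD
#' correlation, draws shape targets from their hyper-distributions (lifted
#' to the Fleishman feasibility floor when needed), then generates each
#' survey with [generate_survey()] under a seed derived deterministically
#' from the master seed.
#'
#' @param spec A [corpus_spec()].
#' @return List with `records` (one tibble for the whole corpus) and
#'   `targets` (tibble of the per-survey moment targets actually used).
#' @export
generate_corpus <- function(spec) {
  set.seed(spec$seed)
  ns <- spec$n_surveys
  r1 <- spec$mean_sd_rho[["child"]]
  r2 <- spec$mean_sd_rho[["wra"]]
  rg <- spec$sd_cross_rho
  # latent order: mean_child, sd_child, sd_wra, mean_wra
  sigma <- rbind(
    c(1, r1, r1 * rg, r1 * rg * r2),
    c(r1, 1, rg, rg * r2),
    c(r1 * rg, rg, 1, r2),
    c(r1 * rg * r2, rg * r2, r2, 1)
  )
  if (inherits(tryCatch(chol(sigma), error = function(e) e), "error")) {
    stop("latent correlation structure is not positive definite",
         call. = FALSE)
  }
  lat <- MASS::mvrnorm(ns, mu = rep(0, 4), Sigma = sigma)
  lat <- matrix(lat, ncol = 4)
  seeds <- sample.int(.Machine$integer.max - 1, 2 * ns)
  ns_child <- round(stats::runif(ns, spec$n_range$child[1],
                                 spec$n_range$child[2]))
  ns_wra <- round(stats::runif(ns, spec$n_range$wra[1],
                               spec$n_range$wra[2]))
  shp <- list()
  for (g in c("child", "wra")) {
    sk <- spec$hyper[[g]]$skew[1] + spec$hyper[[g]]$skew[2] * stats::rnorm(ns)
    ku <- spec$hyper[[g]]$exkurt[1] +
      spec$hyper[[g]]$exkurt[2] * stats::rnorm(ns)
    # the quadratic floor approximation sits up to ~0.08 below the family's
    # true boundary; 0.15 keeps every clamped draw solvable
    ku <- pmax(ku, fleishman_kurtosis_floor(sk) + 0.15)
    shp[[g]] <- list(skew = sk, exkurt = ku)
  }
  tgt <- function(g, latm, lats) {
    h <- spec$hyper[[g]]
    tibble::tibble(
      mean = h$mean[1] + h$mean[2] * latm,
      sd = pmax(h$sd[1] + h$sd[2] * lats, 0.5),
      skew = shp[[g]]$skew, exkurt = shp[[g]]$exkurt
    )
  }
  t_child <- tgt("child", lat[, 1], lat[, 2])
  t_wra <- tgt("wra", lat[, 4], lat[, 3])
  recs <- vector("list", 2 * ns)
  targets <- vector("list", 2 * ns)
  for (i in seq_len(ns)) {
    sid <- sprintf("s%04d", i)
    for (j in 1:2) {
      g <- c("child", "wra")[j]
      tg <- if (g == "child") t_child[i, ] else t_wra[i, ]
      n_i <- if (g == "child") ns_child[i] else ns_wra[i]
      sp <- survey_spec(
        n = n_i, target_mean = tg$mean, target_sd = tg$sd,
        target_skew = tg$skew, target_exkurt = tg$exkurt,
        contamination_rate = spec$contamination_rate,
        rounding_step = spec$rounding_step,
        seed = seeds[2 * (i - 1) + j],
        survey_id = sid, group = g, site = sprintf("site%04d", i)
      )
      k <- 2 * (i - 1) + j
      recs[[k]] <- generate_survey(sp)
      targets[[k]] <- tibble::tibble(
        survey_id = sid, group = g, n = n_i,
        target_mean = tg$mean, target_sd = tg$sd,
        target_skew = tg$skew, target_exkurt = tg$exkurt,
        seed = sp$seed
      )
    }
  }
  list(records = dplyr::bind_rows(recs),
       targets = dplyr::bind_rows(targets))
}
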