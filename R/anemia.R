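#' WHO anemia cutoffs
#'
#' Total anemia is Hb below 11.0 g/dL for children 6-59 months and below
#' 12.0 g/dL for non-pregnant women 15-49 years.
#'
#' @param cutoff_child,cutoff_wra Cutoffs in g/dL.
#' @return A list of class `anemia_rules`.
#' @export
anemia_rules <- function(cutoff_child = 11.0, cutoff_wra = 12.0) {
  stopifnot(cutoff_child > 0, cutoff_wra > 0)
  structure(list(child = cutoff_child, wra = cutoff_wra),
            class = "anemia_rules")
}

#' Altitude adjustment of hemoglobin
#'
#' Subtracts the CDC altitude correction, a polynomial in altitude expressed
#' in thousands of feet, floored at zero so low altitudes never inflate Hb:
#' \eqn{adj = \max(0, -0.032 A + 0.022 A^2)} with
#' \eqn{A = altitude_m \times 0.0032808}. Only needed when input data were
#' recorded unadjusted; survey pipelines normally supply pre-adjusted values.
#'
#' @param hb_raw Unadjusted Hb in g/dL.
#' @param altitude_m Altitude in meters, >= 0 (vectorized, recycled).
#' @return Adjusted Hb in g/dL.
#' @export
adjust_hb_altitude <- function(hb_raw, altitude_m) {
  if (any(altitude_m < 0, na.rm = TRUE)) {
    stop("altitude must be non-negative", call. = FALSE)
  }
  a <- altitude_m * 0.0032808
  hb_raw - pmax(0, -0.032 * a + 0.022 * a^2)
}

#' Classify anemia for one demographic group
#'
#' Strict inequality against the group cutoff: a value exactly at the cutoff
#' is not anemic.
#'
#' @param hb Hb in g/dL (vectorized).
#' @param group `"child"` or `"wra"`.
#' @param rules An [anemia_rules()].
#' @return Logical vector.
#' @export
classify_anemia <- function(hb, group, rules = anemia_rules()) {
  group <- match.arg(group, group_levels)
  hb < rules[[group]]
}

#' Anemia prevalence
#'
#' @param hb Hb values in g/dL, already plausibility-filtered.
#' @inheritParams classify_anemia
#' @return Percentage in \[0, 100\]; `NA` for empty input.
#' @export
anemia_prevalence <- function(hb, group, rules = anemia_rules()) {
  if (length(hb) == 0) return(NA_real_)
  100 * mean(classify_anemia(hb, group, rules))
}
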