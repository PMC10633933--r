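---
title: "Methods: characterizing and quality-screening survey hemoglobin distributions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: characterizing and quality-screening survey hemoglobin distributions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hbqc)
```

## The problem and the model

Field surveys measure hemoglobin (Hb) with portable photometers (HemoCue Hb
301, reporting range 0–25.6 g/dL, display precision 0.1 g/dL) on capillary
blood from children aged 6–59 months and non-pregnant women of reproductive
age (WRA, 15–49 years). Pre-analytic error — finger milking, cuvette
handling, first-drop sampling — widens the observed Hb distribution and
inflates apparent anemia prevalence. The post-collection screen implemented
here rests on an empirical observation: across hundreds of field surveys,
Hb distributions are consistently **left-skewed** and **positively
kurtotic**, WRA more so than children, and WRA SDs run about 0.08 g/dL
above child SDs. These are intrinsic features of Hb in these groups, not
quality defects; what *is* unusual — and therefore worth investigating — is
positive skewness beyond +0.2, excess kurtosis below −0.5, an SD outside
the central bulk of the empirical SD distribution, or more than 1% of
values outside the 4.0–18.0 g/dL plausibility range.

The per-survey characterization uses the bias-adjusted moment estimators

$$G_1 = \frac{\sqrt{n(n-1)}}{n-2}\,\frac{m_3}{m_2^{3/2}}, \qquad
  G_2 = \frac{(n-1)\left[(n+1)\left(m_4/m_2^2 - 3\right) + 6\right]}{(n-2)(n-3)},$$

with $m_r = n^{-1}\sum_i (x_i - \bar x)^r$. $G_2$ is *excess* kurtosis,
centered at zero under normality, so both shape statistics read as
departures from the Gaussian. They require $n \ge 3$ and $n \ge 4$
respectively and a non-constant sample; otherwise the statistic is reported
unavailable and the QC verdict becomes "insufficient data" rather than a
pass.

Statistics are computed on values as recorded at 0.1 g/dL precision; no
unrounding or dithering is applied. All corpus statistics are unweighted:
each survey counts once in across-survey summaries, each record once in
pooled outlier percentages. Cluster design weights are out of scope.

## Screening and exclusion rules, in order

1. **Validity**: values outside 0–25.6 g/dL (inclusive bounds — the device
   reporting range) or unparseable are invalid; rows are kept but excluded
   from analysis.
2. **Deduplication**: rows identical in every field collapse to the first
   occurrence. Rows sharing an id but differing in any field are all kept,
   with a warning — silently dropping a real measurement would distort the
   distribution shape, which is the very thing being screened.
3. **Pregnancy**: pregnant WRA are dropped at ingestion (the reference
   ranges apply to non-pregnant women); a missing flag is treated as
   non-pregnant and logged.
4. **Survey inclusion**: at least 30% of sampled individuals must have a
   valid Hb value, accommodating designs that subsample households for
   anemia. The denominator is an explicit `n_sampled` input; when the
   caller has no subsampling metadata it defaults to the survey's row
   count, making the rule vacuous — a documented, deliberate fallback
   rather than a guess at eligibility counts the data do not contain.
5. **Plausibility**: moments and anemia prevalence use values in
   \[4.0, 18.0\] g/dL (endpoints kept; exclusion strict beyond). The flag
   percentage is computed *before* this exclusion, on all valid values.

The outlier tabulation categorizes each survey's outlier share as `none`
(exactly 0%), `upto1` ((0,1]%), or `gt1` (>1%). The boundary at exactly 1%
is assigned to `upto1` so the three categories partition the surveys; the
">1%" QC rule is strict, so a survey at exactly 1.0% passes.

## The QC rule set

`qc_ruleset()` defaults: skewness max +0.2; excess kurtosis min −0.5; SD
range 1.1–1.55 g/dL (children) and 1.1–1.65 g/dL (WRA); flag maximum 1.0%.
All comparisons are strict, so boundary statistics (SD exactly 1.55/1.65,
G1 exactly 0.2, G2 exactly −0.5, flags exactly 1.0%) pass — the thresholds
are phrased as "above"/"below". Rules fire independently; there is no
composite score, because the flags prompt investigation rather than
automatic exclusion, and a flagged survey is never removed from corpus
summaries by the package itself.

The upper SD bounds are the 90th percentiles of survey-level SDs in the
empirical corpora (after excluding one country subgroup with anomalously
high SDs), rounded to the nearest 0.05 g/dL: P90 1.53 → 1.55 for children,
1.66 → 1.65 for WRA. `derive_sd_thresholds()` reproduces this derivation on
any corpus: upper bound from `p_high = 0.90`, lower from `p_low = 0.025`.
The default lower bound 1.1 is retained as proposed rather than re-derived
— the empirical P2.5 of SD (≈1.09–1.12) motivates it without the proposal
formalizing the derivation. Rounding ties go away from zero (1.525 → 1.55);
the convention is arbitrary but fixed and documented, and matters only when
a percentile lands exactly halfway between steps. Threshold derivation
refuses to run on fewer than 20 surveys per group (configurable), since a
tail percentile of a handful of surveys is noise.

## Corpus analyses

`summarize_corpus()` reports mean, SD and the quantiles {min, P2.5, P10,
P25, P50, P75, P90, P97.5, max} of each survey-level statistic, per group,
optionally alongside a subgroup-exclusion variant driven by a generic
predicate (any country/site/year condition, not a hard-coded subgroup).
Quantiles default to R's type 7 (linear interpolation of order statistics);
the definition id is a visible parameter because percentile conventions
differ across packages, and the package that produced the original
percentiles did not state its algorithm. The median reported for each
survey comes from the same quantile engine at p = 0.5 for internal
consistency.

`spearman_rho()` uses mid-ranks for ties and a two-sided t approximation on
$n-2$ degrees of freedom — adequate at corpus sizes of hundreds of surveys,
where exact permutation p-values are unnecessary. `paired_compare()`
matches surveys by id across groups and applies a paired t test to the
child − WRA differences (the presentation of a mean difference with a 95%
CI implies a t-based interval); a Wilcoxon signed-rank alternative is one
argument away for analysts who prefer a rank test on the visibly
non-normal kurtosis differences. Zero-variance differences yield a
degenerate CI and an explicit warning instead of an error. The sign
convention is fixed: child minus WRA, so the expected SD difference is
negative (≈ −0.07 g/dL).

## Altitude adjustment

Field data normally arrive altitude-adjusted, so adjustment is optional and
applied only to unadjusted records with altitude present. The CDC
polynomial in thousands of feet $A$,
$\mathrm{adj} = \max(0,\, -0.032A + 0.022A^2)$, is used; the field
guidelines' anemia module derives from it. The floor at zero prevents the
polynomial's negative lobe at low altitude from *raising* Hb. A table-based
alternative can be swapped in, since the continuous polynomial and the
guideline lookup tables cannot be distinguished at 0.1 g/dL precision.

## The synthetic-survey generator

The generator stands in for the restricted field microdata. Each survey is
drawn through a third-order Fleishman polynomial
$X = a + bZ + cZ^2 + dZ^3$ ($Z$ standard normal, $a = -c$), whose
coefficients are solved by damped Newton iteration on the closed-form
moment equations to residual $<10^{-9}$, giving exact population control
of mean, SD, skewness and excess kurtosis — the four quantities the QC
screen operates on, which is why this family was chosen over
sinh–arcsinh-type transforms. Near the family's feasibility boundary the
solver warm-starts from an easier target and walks the kurtosis down
adaptively. The commonly used quadratic boundary approximation
$\gamma_2 \ge -1.2264489 + 1.6410373\gamma_1^2$ is a lower envelope of the
true boundary (which sits up to ≈0.08 higher, e.g. −1.1513 at zero skew);
targets below the envelope raise an explicit infeasibility error, and
hyper-distribution draws are lifted to envelope + 0.15, safely inside the
solvable region.

Defaults are the observed field-corpus conditions. Per-survey targets:
children mean 11.1 (SD 0.50), SD 1.39 (0.21), skewness −0.37 (0.26), excess
kurtosis 0.54 (0.67); WRA mean 12.6 (0.57), SD 1.47 (0.23), skewness −0.53
(0.36), excess kurtosis 1.15 (1.17) — each drawn from a normal
hyper-distribution. Latent mean–SD coupling is −0.33 (children) and −0.15
(WRA), reproducing the tendency of high-anemia surveys to show wider
dispersion, and child/WRA SD targets at the same site correlate at 0.52.
The remaining latent cross-correlations are set multiplicatively
(e.g. $\rho_{m_c,s_w} = \rho_{m_c,s_c}\rho_{s_c,s_w}$), the simplest
completion consistent with a shared site-level dispersion factor; the
matrix is checked for positive definiteness. Per-survey sample sizes are
uniform on 175–649 (children) and 99–406 (WRA), spanning the central 90% of
observed field sample sizes. Optional contamination replaces each record
with probability `contamination_rate` by a uniform draw from 1.0–4.0 or
18.0–25.6 g/dL (half low, half high), emulating gross recording errors;
the workflow scripts use 0.001, which reproduces the observed ~0.1%
record-level flag rates. Values are rounded to 0.1 g/dL and clipped to the
device range. Every survey's seed derives deterministically from the master
seed, so corpus CSV output is byte-identical across runs.

What the generator does **not** emulate: cluster/household structure and
design effects, seasonality, covariates, device- or team-level error
structure, and the finite-sample bias patterns of real measurement error.
Passing tests on synthetic corpora therefore demonstrate that the pipeline
computes what it claims on data with known moments — not that the QC
thresholds have any particular sensitivity or specificity against real
field failure modes, which only annotated real data could show.

## Numerical choices and problem sizes

* Sample-moment recovery is verified at $n \in \{400, 10^4, 10^6\}$;
  at $n = 10^6$ the sample mean and SD sit within ±0.01 g/dL, G1 within
  ±0.02 and G2 within ±0.05 of their targets, the residual gap being
  dominated by 0.1 g/dL display rounding (which adds variance
  $0.01/12$) rather than by sampling noise.
* Corpus-level recovery uses 379–400 sites, matching the size of the
  empirical corpora; the across-survey mean of SD recovers its
  hyper-mean within ±0.02 g/dL.
* G1/G2 agree with an independently coded implementation of the same
  estimators to $10^{-12}$ across 1000 random vectors with $n \le 50$; the
  estimators are exactly verifiable on hand-computable fixtures
  ($G_1([0,0,0,1]) = 2$, $G_2([0,0,1,1]) = -6$).
* `round_to_nearest()` divides before flooring and pre-rounds the quotient
  to 9 decimals so that decimal inputs like 1.525 sit exactly on the tie
  despite binary floating point.
* Degenerate inputs are reported, not guessed at: constant samples have
  undefined shape statistics, empty quantile input yields `NA`, a survey
  with zero in-range values is reported with a reason, and zero matched
  pairs is an error.

## Known limitations

The thresholds encoded in `qc_ruleset()` were derived from capillary-blood
HemoCue 301 measurements in high-anemia refugee-setting populations; they
do not transfer to venous blood, other devices, or low-anemia settings
where the mean–SD coupling implies narrower distributions. The 30% validity
rule's denominator depends on sampling metadata the input format cannot
always carry. And because flags are evaluated per rule with no multiplicity
control, screening many surveys will flag some healthy ones by chance —
by construction, about 10% of sound surveys exceed a P90-derived SD bound.
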