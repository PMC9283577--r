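---
title: "Two-sample Mendelian randomization with mrflow: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample Mendelian randomization with mrflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrflow)
```

## The problem

Mendelian randomization (MR) uses genetic variants as instrumental
variables to estimate the causal effect of an exposure on an outcome from
observational data. A variant is a valid instrument when it satisfies three
assumptions: *relevance* (it is associated with the exposure),
*exchangeability* (it shares no confounder with the outcome), and the
*exclusion restriction* (it affects the outcome only through the exposure).
In the two-sample design the SNP–exposure and SNP–outcome associations come
from different GWAS — for example, brain-imaging exposures (white-matter
fractional anisotropy from diffusion tensor imaging, or regional brain
volumes) measured in one cohort, and a binary disease outcome such as
glaucoma from a biobank case-control GWAS. mrflow implements the complete
workflow on GWAS summary statistics: instrument selection, allele
harmonization, causal estimation, and sensitivity analysis, together with a
synthetic summary-statistic generator that makes every stage testable with
known ground truth.

## Instrument selection

Four filters turn an exposure GWAS into an instrument set, in this order:

1. **Genome-wide significance** (`selectByPvalue`): keep variants with
   `p < 5e-8` (strict inequality).
2. **LD clumping** (`ldClump`): rank candidates by ascending p-value (ties
   broken by variant ID), keep the best remaining variant and discard all
   others with squared correlation `r² ≥ 0.001` against it, repeat. The
   squared correlations come from a user-supplied matrix (precomputed from
   a reference panel such as 1000 Genomes) rather than a live lookup, so
   analyses are hermetic and reproducible. No distance window is applied
   beyond the matrix's scope; pairs absent from the matrix are treated as
   uncorrelated, while variants wholly absent follow a configurable policy
   (drop with a warning by default).
3. **Palindrome removal** (`removePalindromic`): A/T and C/G variants are
   removed unconditionally. Their strand cannot be resolved from allele
   labels, and because they are removed outright, allele frequencies are
   never needed for strand inference (missing `eaf` is permitted).
4. **Steiger directionality filter** (`steigerFilter`): a variant that
   explains more variance in the outcome than in the exposure is evidence
   of reverse causation and is dropped (strict inequality; exact ties are
   kept and flagged). Variance explained is computed from the t-statistic
   transformation `r² = t²/(t² + n − 2)`, which needs only fields already
   present in summary statistics. The same form is used for the binary
   outcome as an approximation; an allele-frequency-based
   `r² = 2·maf·(1 − maf)·β²` is available via `r2Method = "eaf"`.
   Diagnostics include a z-test p-value from Fisher-transformed absolute
   correlations.

Between filters 3 and 4, `harmonize` expresses each shared variant's
outcome association on the exposure study's effect allele: matching
alleles are kept, swapped alleles flip the outcome beta's sign, and
base-complement pairs are interpreted as strand differences — labels are
complemented first and the same match/swap logic applied. Irreconcilable
pairs are dropped with a reason. This complement-then-match rule for
non-palindromic strand mismatches is a design choice; because palindromes
are already gone, it is unambiguous.

Every filter returns a subset of its input and logs per-variant drop
reasons, which `runPair` folds into a `SelectionReport` whose stage counts
are non-increasing by construction.

## Estimators

Let `β_Xj ± σ_Xj` and `β_Yj ± σ_Yj` be the harmonized exposure and outcome
associations of instrument `j = 1…J`, with the outcome on the log-odds
scale.

**Wald ratio.** `θ_j = β_Yj/β_Xj` with first-order standard error
`σ_Yj/|β_Xj|`. A second-order SE propagating exposure uncertainty is
available behind a flag (off by default).

**IVW, multiplicative random effects** (`mrIvw`) — the primary estimator.
Weighted least squares of `β_Y` on `β_X` through the origin with weights
`w_j = 1/σ_Yj²`:

    θ̂ = Σ w_j β_Xj β_Yj / Σ w_j β_Xj² ,

equivalently the inverse-variance-weighted mean of the Wald ratios with
first-order weights `β_Xj²/σ_Yj²` (an algebraic identity the test suite
asserts to 1e-10). Cochran's `Q = Σ w_j (β_Yj − θ̂ β_Xj)²` measures
heterogeneity; the multiplicative random-effects SE multiplies the
fixed-effect SE by `max(1, √(Q/(J−1)))`, so overdispersion widens the
interval but homogeneous data are never rewarded with a narrower one.
P-values use the standard normal; all CIs in the package are 95% with
`z = 1.959964`.

**MR-Egger** (`mrEgger`). After orienting each instrument so `β_Xj ≥ 0`,
the same weighted regression with a free intercept. The slope is the
pleiotropy-adjusted causal estimate; the intercept estimates average
directional pleiotropy and its test is the package's first-line pleiotropy
check (valid under the InSIDE assumption — pleiotropic effects independent
of instrument strength). SEs carry the *unfloored* estimated dispersion
`√(Q′/(J−2))` and p-values use the t distribution with `J−2` degrees of
freedom. The floor used for IVW is deliberately not applied here: with the
floor, the intercept t-test becomes structurally conservative (type-I
error ≈ 0.029 at `J = 20` instead of the nominal 0.05, by direct
integration of `Z/max(1, s)` with `s² ~ χ²₁₈/18`), whereas the unfloored
dispersion makes it an exact t-test under homogeneity — matching the
standard weighted-least-squares implementations of this estimator. A
`forceNullIntercept` mode fits through the origin and reproduces the IVW
estimate exactly, which the tests use as an algebraic cross-check.

**Weighted median** (`mrWeightedMedian`). Per-variant ratios `θ_j` with
normalized weights `w_j ∝ β_Xj²/σ_Yj²`; with ratios sorted and
`p_j = s_j − w_j/2` (cumulative weight minus half the variant's own), the
estimate is the ratio where `p_j = 1/2`, or the linear interpolation
between the bracketing ratios. It is consistent whenever instruments
carrying more than half the total weight are valid. The SE comes from a
parametric bootstrap (each replicate redraws every `β_Xj`, `β_Yj` from
normals centred at the observed values with their reported SEs; default
1000 replicates; the seed is a required argument, so no silent
irreproducibility).

`toOddsRatio` exponentiates a log-odds estimate and its CI for
presentation; renderers round odds ratios to 2 decimals and p-values to 3
significant figures, the usual table convention, while full precision is
retained internally.

## Sensitivity analysis

**Cochran's Q** (`cochranQ`) with df `J−1` (IVW form) or `J−2` (Egger
form), upper-tail chi-square p-value.

**MR-PRESSO** (`mrPresso`). The observed residual sum
`RSS = Σ w_j (β_Yj − θ̂₋j β_Xj)²` (each variant judged against the
leave-one-out estimate `θ̂₋j`) is compared with its distribution under a
simulated no-pleiotropy null; the global p is add-one smoothed,
`(1 + #exceed)/(1 + n_sim)`, so it is never exactly zero. Per-variant
outlier p-values come from each variant's own simulated residual
distribution, Bonferroni-multiplied by `J`. When outliers are flagged, the
corrected IVW estimate drops them, and a distortion p-value compares the
raw-minus-corrected difference against differences from removing random
subsets of the same size — a bootstrap-flavoured approximation chosen
because the original algorithm's distortion null is loosely specified.
With fewer than 4 instruments the leave-one-out residual comparison is
degenerate, so the function returns a structured `performed = FALSE`
result with reason `insufficient_snps` rather than raising — downstream
report tables then show the test as not performed, which is also how the
motivating analyses report exposures with only 3 instruments.

**Leave-one-out** (`leaveOneOut`) recomputes the IVW estimate with each
instrument removed; the robustness flag is TRUE when every reduced CI
agrees with the full CI on excluding zero.

## Pipeline and decision rule

`runPair` executes selection → harmonization → estimation → sensitivity
and degrades gracefully with the instrument count: 1 instrument (Wald
only), 2 (+IVW), 3 (+Egger, weighted median, leave-one-out), 4+
(+MR-PRESSO). Each skipped component carries a reason. The decision is
`significant` exactly when the primary p-value is below `alpha` (default
0.05); the primary p is the IVW p-value, or the Wald p-value when a single
instrument survives — the two coincide algebraically at `J = 1`, which is
why the single-instrument case is treated as the IVW degenerate rather
than a separate rule. Egger and the weighted median are reported as
concordance checks but never change the decision.

`runMatrix` screens many exposures against one outcome, deriving a
per-exposure seed as `seed + index` so the whole screen is reproducible
bit for bit. No multiple-testing adjustment is applied by default — the
screening designs this package mirrors report nominal `P < 0.05` across
a couple of hundred exposures, accepting the implied false-positive rate —
but Bonferroni and Benjamini-Hochberg are one config key away
(`adjust = "bonferroni"` or `"BH"`). `renderReports` writes the
estimate/sensitivity/PRESSO/leave-one-out/selection tables as TSV plus a
YAML run-metadata file; identical inputs produce byte-identical files (no
timestamps).

The exported functions are the package's interface; a shell wrapper would
add nothing over `Rscript -e` for this audience, so none is shipped.

## The synthetic-data generator

`generatePair` draws from an explicit generative model:

- true instrument effects `γ_j ~ N(0.15, 0.02²)` on a standardized
  exposure scale;
- pleiotropic effects `α_j = 0` for valid instruments; for the invalid
  fraction, `α_j ~ N(μ_α, σ_α²)` (balanced mode forces `μ_α = 0`); InSIDE
  violation correlates `α_j` with `γ_j` at `ρ = 0.8` by default;
- sampling SEs `σ_Xj = 1/√(2·maf·(1−maf)·n_exp)` and, for the binary
  outcome, `σ_Yj = 1/√(2·maf·(1−maf)·n_out·φ(1−φ))` with case fraction
  `φ` — the defaults (`n_exp = 17706`, `n_out = 218792`,
  `φ = 8591/218792`) mimic an imaging-GWAS exposure against a
  biobank-scale, heavily imbalanced case-control outcome;
- observed effects `β_Xj ~ N(γ_j, σ_Xj)`,
  `β_Yj ~ N(θ·γ_j + α_j, σ_Yj)`; background null variants have `γ = 0`;
- allele labels drawn from non-palindromic pairs, with configurable
  fractions of palindromic variants and of strand-complemented outcome
  labels; LD is block-diagonal with a configurable within-block `r²`.

The default `γ` distribution is chosen so that planted instruments are
genuinely genome-wide significant at the default sample sizes (z-statistics
of roughly 8–14): with much smaller effects the *relevance* assumption
cannot actually be planted, because an effect of 0.05 at `n = 20000` and
`maf = 0.2` has `z ≈ 4` and essentially never reaches `5e-8`.

What the generator deliberately does **not** emulate: realistic
chromosome-scale LD (blocks are exchangeable and constant-`r²`),
individual-level genotypes, winner's-curse selection into the exposure
GWAS, sample overlap between the two studies, and population
stratification. Passing calibration tests on this model therefore shows
the estimators are correctly implemented and calibrated under their own
assumptions, not that real analyses are immune to those additional
complications.

## Calibration studies and problem sizes

The packaged calibration studies (test suite and `scripts/acceptance.R`)
use these study sizes, chosen to keep each run to seconds while leaving
Monte-Carlo noise well inside the asserted bands:

- **Parameter recovery**: `θ = 0.5`, `J = 50`, `n = 20000/20000`,
  200 replicates — mean IVW bias is asserted below 0.02 and empirical 95%
  CI coverage within [0.91, 0.98].
- **Type-I error**: `θ = 0`, `J = 20`, 1000 replicates — IVW and Egger
  intercept rejection at `α = 0.05` asserted within [0.03, 0.08].
- **Weighted-median breakdown**: `θ = 0.5`, `J = 50`, directional
  pleiotropy, 200 replicates at 40% and 60% invalid weight. This scenario
  uses strong instruments (`γ ~ N(0.15, 0.01²)`, maf 0.3–0.5) against a
  large balanced case-control outcome (`n = 600000`, `φ = 0.5`), so the
  per-ratio noise (≈0.03) is small against the planted pleiotropy shift
  (`α/γ ≈ 0.5`). That separation is what makes the median's 50%-weight
  breakdown property visible: below the breakdown point the estimator sits
  on the valid ratios (bias well under 0.05), above it the median lands in
  the contaminated mass (bias far above 0.1). With noisier ratios the two
  regimes blur into each other and neither bound is informative — a
  property of the estimator, not of the implementation.
- **MR-PRESSO**: global-p uniformity under the null (500 replicates at
  `n_sim = 1000`, empirical CDF within ±0.06 of nominal at 0.1/0.5/0.9);
  detection of a planted outlier whose pleiotropic effect is 10× the
  outcome SE (flagged and corrected-closer-to-truth in ≥90% of 100
  replicates); structured degradation at 3 instruments.

All replicate seeds are fixed offsets from a base seed, so every study is
exactly reproducible, and the generator restores the session RNG state
after each draw.

## Numerical choices and degenerate inputs

- CI multiplier fixed at `z = 1.959964`; p-values clamped to the smallest
  positive double so they stay in `(0, 1]`.
- Tie-breaking everywhere is `(p-value ascending, variant ID
  lexicographic)`, making results independent of input order.
- `ldClump` treats a missing *pair* as `r² = 0` but a missing *variant*
  per policy; symmetrization at read time averages asymmetries up to
  1e-6 and rejects larger ones.
- Egger refuses an all-equal `β_X` design (collinearity) and any
  estimator refuses fewer instruments than its minimum (Wald 1, IVW 2,
  Egger/median 3, PRESSO 4) — PRESSO's refusal being a structured result
  rather than an error.
- The weighted-median interpolation detects an exact `p_j = 1/2` within
  1e-12 before interpolating.
- `writeSumStats` serializes floats at 10 significant digits, the
  round-trip contract asserted by the I/O tests.

## Known limitations

Single outcome per run; no proxy-variant lookup for instruments absent
from the outcome study; no mode-based, multivariable, or
contamination-mixture estimators; no funnel/radial plots (tables are the
canonical output). The Steiger filter's binary-outcome variance-explained
is an approximation, flagged above. FinnGen-style outcome betas are
assumed to be supplied on the log-odds scale.
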