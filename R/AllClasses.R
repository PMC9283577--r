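#' @import methods
#' @include utils.R
NULL

#' GWAS summary-statistic table
#'
#' One trait's per-variant summary associations: variant identifier, genomic
#' coordinates, effect/other allele, effect-allele frequency, per-allele
#' effect size (log-odds scale for binary traits), its standard error,
#' p-value and sample size. Rows are `VariantAssociation` records; the class
#' guarantees unique variant IDs, positive SEs, p-values in (0, 1] and
#' single-base A/C/G/T alleles.
#'
#' @slot traitName character(1), name of the trait.
#' @slot traitType `"quantitative"` or `"binary"`.
#' @slot variants data.frame with columns `snp`, `chr`, `pos`, `ea`, `oa`,
#'   `eaf`, `beta`, `se`, `pval`, `n` (canonical dialect).
#' @slot metadata list; provenance such as row-rejection logs and filter
#'   drop records.
#' @aliases SumStats-class
#' @exportClass SumStats
setClass("SumStats",
  representation(traitName = "character", traitType = "character",
                 variants = "data.frame", metadata = "list"),
  prototype(traitName = "trait", traitType = "quantitative",
            metadata = list()))

setValidity("SumStats", function(object) {
  v <- object@variants
  msgs <- character()
  need <- c("snp", "chr", "pos", "ea", "oa", "eaf", "beta", "se", "pval", "n")
  if (!all(need %in% names(v)))
    return(paste("variants must have columns:", paste(need, collapse = ", ")))
  if (length(object@traitName) != 1L) msgs <- c(msgs, "traitName must be length 1")
  if (!object@traitType %in% c("quantitative", "binary"))
    msgs <- c(msgs, "traitType must be 'quantitative' or 'binary'")
  if (nrow(v) > 0) {
    if (anyDuplicated(v$snp)) msgs <- c(msgs, "duplicate variant IDs")
    if (!all(v$ea %in% .BASES) || !all(v$oa %in% .BASES))
      msgs <- c(msgs, "alleles must be single bases A/C/G/T")
    if (any(v$ea == v$oa)) msgs <- c(msgs, "effect and other allele must differ")
    if (any(!is.finite(v$se)) || any(v$se <= 0)) msgs <- c(msgs, "se must be > 0")
    if (any(!is.finite(v$pval)) || any(v$pval <= 0 | v$pval > 1))
      msgs <- c(msgs, "pval must lie in (0, 1]")
    if (any(v$pos < 1, na.rm = TRUE)) msgs <- c(msgs, "pos must be >= 1")
    if (any(v$eaf < 0 | v$eaf > 1, na.rm = TRUE))
      msgs <- c(msgs, "eaf must lie in [0, 1]")
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Pairwise linkage-disequilibrium matrix
#'
#' Square symmetric matrix of r-squared values in \[0, 1\] with unit diagonal,
#' keyed by variant ID. Used by [ldClump()] to prune correlated instruments.
#'
#' @slot variantIds character vector of variant IDs (row/column order).
#' @slot r2 numeric matrix of squared correlations.
#' @aliases LdMatrix-class
#' @exportClass LdMatrix
setClass("LdMatrix",
  representation(variantIds = "character", r2 = "matrix"))

setValidity("LdMatrix", function(object) {
  r2 <- object@r2
  ids <- object@variantIds
  if (nrow(r2) != ncol(r2)) return("r2 must be square")
  if (length(ids) != nrow(r2)) return("variantIds length must match r2 dimension")
  if (anyDuplicated(ids)) return("duplicate variant IDs")
  if (nrow(r2) == 0) return(TRUE)
  if (any(!is.finite(r2))) return("r2 entries must be finite")
  if (any(r2 < 0 | r2 > 1)) return("r2 entries must lie in [0, 1]")
  if (max(abs(r2 - t(r2))) > 1e-8) return("r2 must be symmetric (tolerance 1e-8)")
  if (max(abs(diag(r2) - 1)) > 1e-6) return("r2 diagonal must be 1")
  TRUE
})

#' Harmonized instrument set
#'
#' Exposure and outcome associations for a set of variants expressed on a
#' shared effect allele (the exposure study's effect allele). Produced by
#' [harmonize()]; the input to every causal estimator and sensitivity test.
#'
#' @slot exposureName,outcomeName character(1) trait labels.
#' @slot instruments data.frame with columns `snp`, `beta_exp`, `se_exp`,
#'   `beta_out`, `se_out`, `eaf_exp`, `pval_exp`, `n_exp`, `n_out`, `action`
#'   (one of `kept_as_is`, `flipped`, `strand_complemented`).
#' @slot metadata list; harmonization drop log, Steiger diagnostics.
#' @aliases HarmonizedSet-class
#' @exportClass HarmonizedSet
setClass("HarmonizedSet",
  representation(exposureName = "character", outcomeName = "character",
                 instruments = "data.frame", metadata = "list"),
  prototype(exposureName = "exposure", outcomeName = "outcome",
            metadata = list()))

setValidity("HarmonizedSet", function(object) {
  d <- object@instruments
  need <- c("snp", "beta_exp", "se_exp", "beta_out", "se_out", "eaf_exp",
            "pval_exp", "n_exp", "n_out", "action")
  if (!all(need %in% names(d)))
    return(paste("instruments must have columns:", paste(need, collapse = ", ")))
  if (nrow(d) == 0) return(TRUE)
  msgs <- character()
  if (anyDuplicated(d$snp)) msgs <- c(msgs, "duplicate variant IDs")
  if (any(d$se_exp <= 0) || any(d$se_out <= 0)) msgs <- c(msgs, "SEs must be > 0")
  if (!all(d$action %in% c("kept_as_is", "flipped", "strand_complemented")))
    msgs <- c(msgs, "unknown harmonization action")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Causal-effect estimate
#'
#' One MR method's causal-effect estimate on the exposure's per-unit scale
#' (log-odds of the outcome per exposure unit for a binary outcome), with its
#' standard error, 95% confidence interval, p-value, instrument count, and
#' the residual-overdispersion multiplier applied to the SE (1 when not
#' applicable).
#'
#' @slot method one of `wald`, `ivw_mre`, `egger_slope`, `egger_intercept`,
#'   `weighted_median`.
#' @slot theta,se,ciLow,ciHigh,pval numeric(1).
#' @slot nSnp integer(1) instruments used.
#' @slot scaleFactor numeric(1) >= 0 overdispersion multiplier.
#' @aliases CausalEstimate-class
#' @exportClass CausalEstimate
setClass("CausalEstimate",
  representation(method = "character", theta = "numeric", se = "numeric",
                 ciLow = "numeric", ciHigh = "numeric", pval = "numeric",
                 nSnp = "integer", scaleFactor = "numeric"))

setValidity("CausalEstimate", function(object) {
  msgs <- character()
  minSnp <- c(wald = 1L, ivw_mre = 2L, egger_slope = 3L,
              egger_intercept = 3L, weighted_median = 3L)
  if (!object@method %in% names(minSnp)) return("unknown method")
  if (object@se <= 0) msgs <- c(msgs, "se must be > 0")
  if (object@pval <= 0 || object@pval > 1) msgs <- c(msgs, "pval must lie in (0, 1]")
  if (object@ciLow > object@theta || object@theta > object@ciHigh)
    msgs <- c(msgs, "CI must bracket theta")
  if (object@nSnp < minSnp[[object@method]])
    msgs <- c(msgs, sprintf("method '%s' needs >= %d instruments",
                            object@method, minSnp[[object@method]]))
  if (object@scaleFactor < 0) msgs <- c(msgs, "scaleFactor must be >= 0")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Odds-ratio presentation of a causal estimate
#'
#' @slot or,orLow,orHigh numeric(1), strictly positive; `exp()` of the
#'   log-odds estimate and its CI bounds.
#' @slot pval numeric(1).
#' @aliases OddsRatio-class
#' @exportClass OddsRatio
setClass("OddsRatio",
  representation(or = "numeric", orLow = "numeric", orHigh = "numeric",
                 pval = "numeric"))

setValidity("OddsRatio", function(object) {
  if (object@or <= 0 || object@orLow <= 0 || object@orHigh <= 0)
    return("odds ratios must be strictly positive")
  if (object@orLow > object@or || object@or > object@orHigh)
    return("CI must bracket the point estimate")
  TRUE
})

#' Heterogeneity (Cochran's Q) test result
#'
#' @slot method `"ivw"` or `"egger"` (fitted model the residuals come from).
#' @slot Q numeric(1) >= 0.
#' @slot df integer(1) >= 1.
#' @slot pval numeric(1), upper-tail chi-square probability of `Q` at `df`.
#' @aliases HeterogeneityResult-class
#' @exportClass HeterogeneityResult
setClass("HeterogeneityResult",
  representation(method = "character", Q = "numeric", df = "integer",
                 pval = "numeric"))

setValidity("HeterogeneityResult", function(object) {
  if (!object@method %in% c("ivw", "egger")) return("method must be 'ivw' or 'egger'")
  if (object@Q < 0) return("Q must be >= 0")
  if (object@df < 1) return("df must be >= 1")
  if (abs(object@pval - stats::pchisq(object@Q, object@df, lower.tail = FALSE)) > 1e-12)
    return("pval must be the upper-tail chi-square probability of Q")
  TRUE
})

#' MR-PRESSO result
#'
#' Global residual-sum pleiotropy test, per-variant outlier flags
#' (Bonferroni-adjusted empirical p-values), and the distortion comparison of
#' the outlier-corrected estimate against the raw one. When fewer than four
#' instruments are available the test is not performed and
#' `notPerformedReason` says why (a structured result, not an error).
#'
#' @slot performed logical(1).
#' @slot rssObs observed weighted residual sum of squares.
#' @slot globalPval empirical global p (add-one smoothed).
#' @slot outlierIds flagged variant IDs.
#' @slot outlierPvals named per-variant Bonferroni-adjusted empirical p-values.
#' @slot distortionPval distortion-test p (NA when no outliers flagged).
#' @slot thetaRaw,thetaCorrected IVW estimates on all/non-outlier instruments.
#' @slot nSim integer(1) simulated null datasets.
#' @slot seed integer(1) RNG seed used.
#' @slot notPerformedReason character(1) or NA.
#' @aliases PressoResult-class
#' @exportClass PressoResult
setClass("PressoResult",
  representation(performed = "logical", rssObs = "numeric",
                 globalPval = "numeric", outlierIds = "character",
                 outlierPvals = "numeric", distortionPval = "numeric",
                 thetaRaw = "numeric", thetaCorrected = "numeric",
                 nSim = "integer", seed = "integer",
                 notPerformedReason = "character"))

setValidity("PressoResult", function(object) {
  if (!object@performed) {
    if (is.na(object@notPerformedReason))
      return("not-performed result must carry a reason")
    if (!all(is.na(c(object@rssObs, object@globalPval, object@thetaRaw,
                     object@thetaCorrected, object@distortionPval))))
      return("numeric fields must be NA when the test was not performed")
  }
  TRUE
})

#' Leave-one-out robustness result
#'
#' Per-variant IVW re-estimates with each instrument removed in turn,
#' alongside the all-instrument estimate, and a robustness flag that is TRUE
#' when every leave-one-out CI agrees with the full CI on whether zero is
#' excluded.
#'
#' @slot rows data.frame (`snp`, `theta`, `se`, `ciLow`, `ciHigh`, `pval`),
#'   one row per excluded variant.
#' @slot full [CausalEstimate-class] on all instruments.
#' @slot robust logical(1).
#' @aliases LeaveOneOutResult-class
#' @exportClass LeaveOneOutResult
setClass("LeaveOneOutResult",
  representation(rows = "data.frame", full = "CausalEstimate",
                 robust = "logical"))

#' Selection-stage accounting
#'
#' Instrument counts after each selection stage (candidates, p-value filter,
#' LD clumping, palindrome removal, outcome overlap/harmonization, Steiger
#' filter) and the per-variant drop reasons. Counts are non-increasing
#' through the stage sequence.
#'
#' @slot stages data.frame with columns `stage`, `count`.
#' @slot drops data.frame with columns `snp`, `stage`, `reason`.
#' @aliases SelectionReport-class
#' @exportClass SelectionReport
setClass("SelectionReport",
  representation(stages = "data.frame", drops = "data.frame"))

setValidity("SelectionReport", function(object) {
  if (!all(c("stage", "count") %in% names(object@stages)))
    return("stages needs columns stage, count")
  if (nrow(object@stages) > 1 && any(diff(object@stages$count) > 0))
    return("stage counts must be non-increasing")
  TRUE
})

#' Synthetic two-sample GWAS scenario
#'
#' Generative-model parameters for [generatePair()]: the planted causal
#' effect, instrument count and strength distribution, the pleiotropy model
#' (none/balanced/directional, optionally correlated with instrument strength
#' to violate the InSIDE assumption), per-study sample sizes and outcome
#' case fraction, allele-frequency range, background null variants, LD block
#' structure, and the mandatory RNG seed.
#'
#' @slot thetaTrue planted causal effect (log-odds per exposure SD).
#' @slot J integer(1), instrument count.
#' @slot invalidFraction fraction of instruments given pleiotropic effects.
#' @slot pleiotropyMode `"none"`, `"balanced"` or `"directional"`.
#' @slot pleiotropyMean,pleiotropySd location/scale of pleiotropic effects
#'   (mean forced to 0 for balanced mode).
#' @slot insideViolated logical; correlate pleiotropy with instrument strength.
#' @slot insideRho correlation used when `insideViolated`.
#' @slot gammaMean,gammaSd distribution of true SNP-exposure effects.
#' @slot nExp,nOut per-study sample sizes.
#' @slot caseFraction outcome case fraction (binary outcome SE inflation).
#' @slot mafRange length-2 numeric in (0, 0.5].
#' @slot nNullVariants background variants with zero true effect.
#' @slot ldBlockSizes integer block sizes over all variants (empty = all
#'   independent); must sum to `J + nNullVariants` when non-empty.
#' @slot ldWithinBlockR2 within-block squared correlation.
#' @slot palindromicFraction,strandFlipFraction fractions of variants given
#'   A/T-C/G allele pairs, resp. complemented outcome allele labels.
#' @slot seed integer(1), mandatory.
#' @aliases MRScenario-class
#' @exportClass MRScenario
setClass("MRScenario",
  representation(thetaTrue = "numeric", J = "integer",
                 invalidFraction = "numeric", pleiotropyMode = "character",
                 pleiotropyMean = "numeric", pleiotropySd = "numeric",
                 insideViolated = "logical", insideRho = "numeric",
                 gammaMean = "numeric", gammaSd = "numeric",
                 nExp = "integer", nOut = "integer", caseFraction = "numeric",
                 mafRange = "numeric", nNullVariants = "integer",
                 ldBlockSizes = "integer", ldWithinBlockR2 = "numeric",
                 palindromicFraction = "numeric", strandFlipFraction = "numeric",
                 seed = "integer"))

setValidity("MRScenario", function(object) {
  msgs <- character()
  if (object@J < 1) msgs <- c(msgs, "J must be >= 1")
  if (object@invalidFraction < 0 || object@invalidFraction > 1)
    msgs <- c(msgs, "invalidFraction must lie in [0, 1]")
  if (!object@pleiotropyMode %in% c("none", "balanced", "directional"))
    msgs <- c(msgs, "pleiotropyMode must be none/balanced/directional")
  if (object@pleiotropySd < 0 || object@gammaSd < 0)
    msgs <- c(msgs, "sds must be >= 0")
  if (object@nExp < 1 || object@nOut < 1) msgs <- c(msgs, "sample sizes must be positive")
  if (object@caseFraction <= 0 || object@caseFraction >= 1)
    msgs <- c(msgs, "caseFraction must lie in (0, 1)")
  if (length(object@mafRange) != 2 || object@mafRange[1] <= 0 ||
      object@mafRange[1] > object@mafRange[2] || object@mafRange[2] > 0.5)
    msgs <- c(msgs, "mafRange must satisfy 0 < low <= high <= 0.5")
  if (object@nNullVariants < 0) msgs <- c(msgs, "nNullVariants must be >= 0")
  if (length(object@ldBlockSizes) &&
      sum(object@ldBlockSizes) != object@J + object@nNullVariants)
    msgs <- c(msgs, "ldBlockSizes must sum to J + nNullVariants")
  if (object@ldWithinBlockR2 < 0 || object@ldWithinBlockR2 > 1)
    msgs <- c(msgs, "ldWithinBlockR2 must lie in [0, 1]")
  if (is.na(object@seed)) msgs <- c(msgs, "seed is mandatory")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Result of one exposure-outcome MR analysis
#'
#' Everything [runPair()] produces for one exposure: the selection
#' accounting, the harmonized instruments, all estimates computed at the
#' available instrument count, heterogeneity/PRESSO/leave-one-out
#' diagnostics, the skip ledger for stages that could not run, and the
#' primary decision (IVW p-value against the configured alpha).
#'
#' @slot exposureName character(1).
#' @slot selection [SelectionReport-class].
#' @slot instruments [HarmonizedSet-class].
#' @slot estimates named list of [CausalEstimate-class] objects.
#' @slot heterogeneity named list of [HeterogeneityResult-class] objects.
#' @slot presso [PressoResult-class] or NULL.
#' @slot leaveOneOut [LeaveOneOutResult-class] or NULL.
#' @slot skipped named character; reason per skipped analysis component.
#' @slot decision `"significant"` or `"not_significant"`.
#' @slot alpha numeric(1) decision threshold.
#' @slot primaryPval numeric(1) p-value the decision is based on (IVW; Wald
#'   when only one instrument survives; NA when none).
#' @aliases PairResult-class
#' @exportClass PairResult
setClass("PairResult",
  representation(exposureName = "character", selection = "SelectionReport",
                 instruments = "HarmonizedSet", estimates = "list",
                 heterogeneity = "list", presso = "ANY", leaveOneOut = "ANY",
                 skipped = "character", decision = "character",
                 alpha = "numeric", primaryPval = "numeric"))

setValidity("PairResult", function(object) {
  if (!object@decision %in% c("significant", "not_significant"))
    return("decision must be significant/not_significant")
  sig <- is.finite(object@primaryPval) && object@primaryPval < object@alpha
  if (sig != (object@decision == "significant"))
    return("decision must equal (primary p < alpha)")
  TRUE
})

#' Multi-exposure screen report
#'
#' Ordered collection of [PairResult-class] objects from [runMatrix()], the
#' subset meeting the decision rule, and run metadata (thresholds, seeds)
#' sufficient to re-run the screen reproducibly.
#'
#' @slot pairs named list of [PairResult-class].
#' @slot significant character vector of exposure names passing the rule.
#' @slot metadata list (config, per-exposure seeds, package version).
#' @aliases MatrixReport-class
#' @exportClass MatrixReport
setClass("MatrixReport",
  representation(pairs = "list", significant = "character",
                 metadata = "list"))

setValidity("MatrixReport", function(object) {
  sig <- vapply(object@pairs, function(p) p@decision == "significant", logical(1))
  if (!identical(sort(unname(object@significant)),
                 sort(names(object@pairs)[sig])))
    return("significant subset must equal the pairs passing the decision rule")
  TRUE
})
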