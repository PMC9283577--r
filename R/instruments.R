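#' @include accessors.R
NULL

## Instrument selection: genome-wide significance filter, greedy LD
## clumping, unconditional palindrome removal, allele harmonization, and
## Steiger directionality filtering. Each filter returns a subset of its
## input and records the variants it dropped in the result's metadata
## (`mrMetadata(x)$lastFilter`), which the pipeline folds into a
## SelectionReport.

.subsetSumStats <- function(x, keepIdx, stage, dropReasons) {
  d <- variants(x)
  dropSnp <- d$snp[setdiff(seq_len(nrow(d)), keepIdx)]
  dropped <- data.frame(snp = dropSnp, stage = rep(stage, length(dropSnp)),
                        reason = dropReasons, stringsAsFactors = FALSE)
  d <- d[keepIdx, , drop = FALSE]
  rownames(d) <- NULL
  md <- x@metadata
  md$lastFilter <- list(stage = stage, dropped = dropped)
  initialize(x, variants = d, metadata = md)
}

#' Genome-wide significance filter
#'
#' Keeps variants with `pval < threshold` (strict inequality, so a p-value
#' exactly at the threshold is dropped). Record order is preserved; an
#' empty result is valid.
#'
#' @param x a [SumStats-class] object.
#' @param threshold p-value threshold in (0, 1); default the conventional
#'   genome-wide significance level 5e-8.
#' @return a [SumStats-class] subset of `x`.
#' @export
setMethod("selectByPvalue", "SumStats", function(x, threshold = 5e-8) {
  .assertScalarNumber(threshold, "threshold")
  if (threshold <= 0 || threshold >= 1)
    stop("'threshold' must lie in (0, 1)", call. = FALSE)
  keep <- which(variants(x)$pval < threshold)
  .subsetSumStats(x, keep, "pass_pvalue",
                  rep("pval_above_threshold",
                      nVariants(x) - length(keep)))
})

#' Greedy LD clumping
#'
#' Prunes correlated variants so the retained instruments are approximately
#' independent: candidates are ranked by ascending p-value (ties broken by
#' variant ID), and repeatedly the best remaining variant is kept while all
#' others with squared correlation `>= r2Threshold` against it are
#' discarded. The output is ordered by p-value. Variant pairs absent from
#' the matrix are treated as uncorrelated when both variants are present;
#' variants wholly absent from the matrix follow `missingPolicy`.
#'
#' @param x a [SumStats-class] object.
#' @param ld an [LdMatrix-class] with the candidate variants.
#' @param r2Threshold squared-correlation threshold; default 0.001.
#' @param missingPolicy what to do with variants absent from `ld`:
#'   `"drop"` (default, with a warning), `"keep"` (treat as independent), or
#'   `"error"`.
#' @return a [SumStats-class] subset of `x`, ordered by ascending p-value.
#' @export
setMethod("ldClump", "SumStats",
  function(x, ld, r2Threshold = 0.001,
           missingPolicy = c("drop", "keep", "error")) {
  missingPolicy <- match.arg(missingPolicy)
  stopifnot(is(ld, "LdMatrix"))
  .assertScalarNumber(r2Threshold, "r2Threshold")
  d <- variants(x)
  inLd <- d$snp %in% ld@variantIds
  if (any(!inLd)) {
    if (missingPolicy == "error")
      stop(sprintf("%d variant(s) missing from the LD matrix", sum(!inLd)),
           call. = FALSE)
    if (missingPolicy == "drop")
      warning(sprintf("dropping %d variant(s) missing from the LD matrix",
                      sum(!inLd)), call. = FALSE)
  }
  candIdx <- if (missingPolicy == "drop") which(inLd) else seq_len(nrow(d))
  ord <- candIdx[order(d$pval[candIdx], d$snp[candIdx])]
  kept <- integer()
  reasons <- character(nrow(d))
  reasons[setdiff(seq_len(nrow(d)), candIdx)] <- "missing_from_ld_matrix"
  remaining <- ord
  while (length(remaining)) {
    best <- remaining[1]
    kept <- c(kept, best)
    remaining <- remaining[-1]
    if (!length(remaining)) break
    if (d$snp[best] %in% ld@variantIds) {
      others <- remaining[d$snp[remaining] %in% ld@variantIds]
      if (length(others)) {
        r2 <- ld@r2[d$snp[best], d$snp[others]]
        prune <- others[r2 >= r2Threshold]
        if (length(prune)) {
          reasons[prune] <- sprintf("ld_with_%s", d$snp[best])
          remaining <- setdiff(remaining, prune)
        }
      }
    }
  }
  dropIdx <- setdiff(seq_len(nrow(d)), kept)
  .subsetSumStats(x, kept, "pass_clump", reasons[dropIdx])
})

#' Remove palindromic variants
#'
#' Drops every A/T and C/G variant unconditionally, regardless of allele
#' frequency: the strand of a palindromic variant cannot be resolved from
#' its alleles, so no frequency-based rescue is attempted.
#'
#' @param x a [SumStats-class] object.
#' @return a [SumStats-class] subset of `x`.
#' @export
setMethod("removePalindromic", "SumStats", function(x) {
  d <- variants(x)
  pal <- .isPalindromic(d$ea, d$oa)
  .subsetSumStats(x, which(!pal), "pass_palindrome",
                  rep("palindromic_alleles", sum(pal)))
})

#' Harmonize exposure and outcome summary statistics
#'
#' Expresses each shared variant's outcome association on the exposure
#' study's effect allele. If the outcome alleles match, the record is kept
#' as is; if they are swapped, the outcome beta is negated (`flipped`); if
#' they are the base-complement pair (the outcome study reported the other
#' strand), the labels are complemented first and the same logic applied
#' (`strand_complemented`). Irreconcilable allele pairs and variants absent
#' from the outcome study are dropped with a reason. Palindromic variants
#' should be removed beforehand ([removePalindromic()]). Output is ordered
#' by ascending exposure p-value (ties by variant ID).
#'
#' @param exposure,outcome [SumStats-class] objects.
#' @return a [HarmonizedSet-class]; `mrMetadata(x)$dropped` logs the drops.
#' @export
setMethod("harmonize", signature("SumStats", "SumStats"),
  function(exposure, outcome) {
  de <- variants(exposure)
  do <- variants(outcome)
  m <- match(de$snp, do$snp)
  drops <- data.frame(snp = character(), reason = character(),
                      stringsAsFactors = FALSE)
  rows <- vector("list", nrow(de))
  for (i in seq_len(nrow(de))) {
    j <- m[i]
    if (is.na(j)) {
      drops <- rbind(drops, data.frame(snp = de$snp[i],
                                       reason = "absent_in_outcome"))
      next
    }
    ea <- de$ea[i]; oa <- de$oa[i]
    eaO <- do$ea[j]; oaO <- do$oa[j]
    action <- NA_character_; betaOut <- NA_real_
    if (eaO == ea && oaO == oa) {
      action <- "kept_as_is"; betaOut <- do$beta[j]
    } else if (eaO == oa && oaO == ea) {
      action <- "flipped"; betaOut <- -do$beta[j]
    } else {
      ceaO <- .complement(eaO); coaO <- .complement(oaO)
      if (ceaO == ea && coaO == oa) {
        action <- "strand_complemented"; betaOut <- do$beta[j]
      } else if (ceaO == oa && coaO == ea) {
        action <- "strand_complemented"; betaOut <- -do$beta[j]
      }
    }
    if (is.na(action)) {
      drops <- rbind(drops, data.frame(snp = de$snp[i],
                                       reason = "allele_mismatch"))
      next
    }
    rows[[i]] <- data.frame(
      snp = de$snp[i], beta_exp = de$beta[i], se_exp = de$se[i],
      beta_out = betaOut, se_out = do$se[j], eaf_exp = de$eaf[i],
      pval_exp = de$pval[i], n_exp = de$n[i], n_out = do$n[j],
      action = action, stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  inst <- if (length(rows)) do.call(rbind, rows) else .emptyInstruments()
  inst <- inst[order(inst$pval_exp, inst$snp), , drop = FALSE]
  rownames(inst) <- NULL
  HarmonizedSet(inst, exposureName = traitName(exposure),
                outcomeName = traitName(outcome),
                metadata = list(dropped = drops))
})

## Variance explained by one variant from its summary statistics, via the
## t-statistic transformation r^2 = t^2 / (t^2 + n - 2).
.r2FromT <- function(beta, se, n) {
  t2 <- (beta / se)^2
  t2 / (t2 + n - 2)
}

## r^2 approximation from allele frequency: 2 maf (1-maf) beta^2 on a
## standardized trait (optional route for binary outcomes).
.r2FromEaf <- function(beta, eaf) 2 * eaf * (1 - eaf) * beta^2

#' Steiger directionality filter
#'
#' Drops variants whose summary statistics explain more variance in the
#' outcome than in the exposure — evidence the variant is primarily an
#' outcome variant and the causal arrow points the wrong way. Variance
#' explained is computed from the t-statistic transformation
#' `r2 = t^2 / (t^2 + n - 2)` (the same form is used for the binary outcome
#' as an approximation; `r2Method = "eaf"` switches to an allele-frequency
#' based `r2 = 2 maf (1 - maf) beta^2`). Exact ties are retained and
#' flagged. Diagnostics report both variance-explained values and the
#' Steiger z-test p-value from comparing Fisher-transformed absolute
#' correlations.
#'
#' @param x a [HarmonizedSet-class].
#' @param nExp,nOut sample sizes; default to each variant's `n_exp`/`n_out`.
#' @param r2Method `"tstat"` (default) or `"eaf"` for the outcome side.
#' @return a [HarmonizedSet-class] subset; `mrMetadata(x)$steiger` holds the
#'   per-variant diagnostics (`snp`, `r2_exp`, `r2_out`, `steiger_pval`,
#'   `kept`, `tie`).
#' @export
setMethod("steigerFilter", "HarmonizedSet",
  function(x, nExp = NULL, nOut = NULL, r2Method = c("tstat", "eaf")) {
  r2Method <- match.arg(r2Method)
  d <- instruments(x)
  if (nrow(d) == 0) return(x)
  nE <- if (is.null(nExp)) d$n_exp else rep_len(nExp, nrow(d))
  nO <- if (is.null(nOut)) d$n_out else rep_len(nOut, nrow(d))
  if (any(!is.finite(nE)) || any(!is.finite(nO)))
    stop("sample sizes required for Steiger filtering (per-variant n or ",
         "'nExp'/'nOut')", call. = FALSE)
  if (any(nE < 3) || any(nO < 3))
    stop("Steiger filtering needs n >= 3 in both studies", call. = FALSE)
  r2X <- .r2FromT(d$beta_exp, d$se_exp, nE)
  r2Y <- if (r2Method == "eaf") {
    if (any(!is.finite(d$eaf_exp)))
      stop("r2Method = 'eaf' needs effect-allele frequencies", call. = FALSE)
    .r2FromEaf(d$beta_out, d$eaf_exp)
  } else {
    .r2FromT(d$beta_out, d$se_out, nO)
  }
  # Fisher z on |r|; z-test for difference of the two correlations.
  zX <- atanh(sqrt(pmin(r2X, 1 - 1e-12)))
  zY <- atanh(sqrt(pmin(r2Y, 1 - 1e-12)))
  zStat <- (zX - zY) / sqrt(1 / (nE - 3) + 1 / (nO - 3))
  pSteiger <- .pNorm2(zStat)
  tie <- r2X == r2Y
  keep <- r2Y <= r2X              # strict r2Y > r2X drops; ties retained
  diag <- data.frame(snp = d$snp, r2_exp = r2X, r2_out = r2Y,
                     steiger_pval = pSteiger, kept = keep, tie = tie,
                     stringsAsFactors = FALSE)
  dropped <- data.frame(snp = d$snp[!keep],
                        stage = rep("pass_steiger", sum(!keep)),
                        reason = rep("outcome_variance_exceeds_exposure",
                                     sum(!keep)),
                        stringsAsFactors = FALSE)
  inst <- d[keep, , drop = FALSE]
  rownames(inst) <- NULL
  md <- x@metadata
  md$steiger <- diag
  md$lastFilter <- list(stage = "pass_steiger", dropped = dropped)
  initialize(x, instruments = inst, metadata = md)
})
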