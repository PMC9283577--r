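#' @include AllClasses.R AllGenerics.R
NULL

#' Accessors for SumStats objects
#'
#' @param x a [SumStats-class] object.
#' @return `traitName` and `traitType` return character(1); `variants` the
#'   underlying data.frame; `nVariants` the row count.
#' @name SumStats-accessors
#' @examples
#' ss <- SumStats(data.frame(snp = "rs1", chr = "1", pos = 100, ea = "A",
#'                           oa = "G", eaf = 0.3, beta = 0.1, se = 0.01,
#'                           pval = 1e-10, n = 20000),
#'                traitName = "FA", traitType = "quantitative")
#' nVariants(ss)
NULL

#' @rdname SumStats-accessors
#' @export
setMethod("traitName", "SumStats", function(x) x@traitName)

#' @rdname SumStats-accessors
#' @export
setMethod("traitType", "SumStats", function(x) x@traitType)

#' @rdname SumStats-accessors
#' @export
setMethod("variants", "SumStats", function(x) x@variants)

#' @rdname SumStats-accessors
#' @export
setMethod("nVariants", "SumStats", function(x) nrow(x@variants))

#' Accessors for HarmonizedSet objects
#'
#' @param x a [HarmonizedSet-class] object.
#' @return `instruments` returns the per-variant data.frame; `nInstruments`
#'   its row count; the name accessors character(1).
#' @name HarmonizedSet-accessors
NULL

#' @rdname HarmonizedSet-accessors
#' @export
setMethod("instruments", "HarmonizedSet", function(x) x@instruments)

#' @rdname HarmonizedSet-accessors
#' @export
setMethod("nInstruments", "HarmonizedSet", function(x) nrow(x@instruments))

#' @rdname HarmonizedSet-accessors
#' @export
setMethod("exposureName", "HarmonizedSet", function(x) x@exposureName)

#' @rdname HarmonizedSet-accessors
#' @export
setMethod("outcomeName", "HarmonizedSet", function(x) x@outcomeName)

#' Provenance metadata attached to data containers
#'
#' Row-rejection logs from [readSumStats()], filter drop records, Steiger
#' diagnostics and similar per-object provenance.
#'
#' @param x a [SumStats-class] or [HarmonizedSet-class] object.
#' @return a named list.
#' @export
#' @rdname mrMetadata
setMethod("mrMetadata", "SumStats", function(x) x@metadata)

#' @rdname mrMetadata
#' @export
setMethod("mrMetadata", "HarmonizedSet", function(x) x@metadata)

#' Construct a SumStats object from a data.frame
#'
#' Canonical columns: `snp`, `chr`, `pos`, `ea`, `oa`, `eaf`, `beta`, `se`,
#' `pval`, `n`. Missing optional columns (`chr`, `pos`, `eaf`, `n`) are
#' filled with NA; alleles are upper-cased.
#'
#' @param variants data.frame of per-variant associations.
#' @param traitName trait label.
#' @param traitType `"quantitative"` or `"binary"`.
#' @param metadata optional provenance list.
#' @return a validated [SumStats-class] object.
#' @export
SumStats <- function(variants, traitName = "trait",
                     traitType = c("quantitative", "binary"),
                     metadata = list()) {
  traitType <- match.arg(traitType)
  tmpl <- .emptyVariants()
  for (col in names(tmpl))
    if (is.null(variants[[col]])) variants[[col]] <- rep(NA, nrow(variants))
  variants <- variants[names(tmpl)]
  variants$snp <- as.character(variants$snp)
  variants$chr <- as.character(variants$chr)
  variants$pos <- as.integer(variants$pos)
  variants$ea <- toupper(as.character(variants$ea))
  variants$oa <- toupper(as.character(variants$oa))
  for (col in c("eaf", "beta", "se", "pval", "n"))
    variants[[col]] <- as.numeric(variants[[col]])
  rownames(variants) <- NULL
  new("SumStats", traitName = traitName, traitType = traitType,
      variants = variants, metadata = metadata)
}

#' Construct an LdMatrix
#'
#' @param r2 square symmetric numeric matrix of r-squared values.
#' @param variantIds variant IDs; defaults to `rownames(r2)`.
#' @return a validated [LdMatrix-class] object.
#' @export
LdMatrix <- function(r2, variantIds = rownames(r2)) {
  r2 <- as.matrix(r2)
  if (is.null(variantIds))
    stop("variant IDs are required (rownames or 'variantIds')", call. = FALSE)
  dimnames(r2) <- list(variantIds, variantIds)
  new("LdMatrix", variantIds = as.character(variantIds), r2 = r2)
}

#' Construct a HarmonizedSet from a data.frame
#'
#' Mostly useful for simulation studies and tests; [harmonize()] is the
#' normal route. Missing optional columns (`eaf_exp`, `pval_exp`, `n_exp`,
#' `n_out`, `action`) are filled with defaults.
#'
#' @param instruments data.frame with at least `snp`, `beta_exp`, `se_exp`,
#'   `beta_out`, `se_out`.
#' @param exposureName,outcomeName trait labels.
#' @param metadata optional provenance list.
#' @return a validated [HarmonizedSet-class] object.
#' @export
HarmonizedSet <- function(instruments, exposureName = "exposure",
                          outcomeName = "outcome", metadata = list()) {
  tmpl <- .emptyInstruments()
  if (is.null(instruments$action))
    instruments$action <- rep("kept_as_is", nrow(instruments))
  if (is.null(instruments$pval_exp))
    instruments$pval_exp <- .pNorm2(instruments$beta_exp / instruments$se_exp)
  for (col in names(tmpl))
    if (is.null(instruments[[col]])) instruments[[col]] <- rep(NA, nrow(instruments))
  instruments <- instruments[names(tmpl)]
  instruments$snp <- as.character(instruments$snp)
  instruments$action <- as.character(instruments$action)
  for (col in setdiff(names(tmpl), c("snp", "action")))
    instruments[[col]] <- as.numeric(instruments[[col]])
  rownames(instruments) <- NULL
  new("HarmonizedSet", exposureName = exposureName, outcomeName = outcomeName,
      instruments = instruments, metadata = metadata)
}

.newEstimate <- function(method, theta, se, pval, nSnp, scaleFactor = 1) {
  new("CausalEstimate", method = method, theta = theta, se = se,
      ciLow = theta - .Z95 * se, ciHigh = theta + .Z95 * se,
      pval = pval, nSnp = as.integer(nSnp), scaleFactor = scaleFactor)
}

.newHeterogeneity <- function(method, Q, df) {
  new("HeterogeneityResult", method = method, Q = Q, df = as.integer(df),
      pval = stats::pchisq(Q, df, lower.tail = FALSE))
}

## show methods --------------------------------------------------------------

setMethod("show", "SumStats", function(object) {
  cat(sprintf("SumStats: %s (%s), %d variants\n",
              object@traitName, object@traitType, nrow(object@variants)))
  rej <- object@metadata$rejections
  if (!is.null(rej) && nrow(rej))
    cat(sprintf("  %d rows rejected at read time\n", nrow(rej)))
})

setMethod("show", "LdMatrix", function(object) {
  cat(sprintf("LdMatrix: %d variants\n", length(object@variantIds)))
})

setMethod("show", "HarmonizedSet", function(object) {
  cat(sprintf("HarmonizedSet: %s -> %s, %d instruments\n",
              object@exposureName, object@outcomeName,
              nrow(object@instruments)))
  if (nrow(object@instruments))
    print(table(object@instruments$action))
})

setMethod("show", "CausalEstimate", function(object) {
  cat(sprintf("%s: theta = %.4f (se %.4f), 95%% CI [%.4f, %.4f], p = %.3g, %d SNPs\n",
              object@method, object@theta, object@se, object@ciLow,
              object@ciHigh, object@pval, object@nSnp))
  if (object@scaleFactor != 1)
    cat(sprintf("  overdispersion scale %.3f\n", object@scaleFactor))
})

setMethod("show", "OddsRatio", function(object) {
  cat(sprintf("OR %.2f, 95%% CI %.2f-%.2f, p = %.3g\n",
              object@or, object@orLow, object@orHigh, object@pval))
})

setMethod("show", "HeterogeneityResult", function(object) {
  cat(sprintf("Cochran's Q (%s): Q = %.3f, df = %d, p = %.3g\n",
              object@method, object@Q, object@df, object@pval))
})

setMethod("show", "PressoResult", function(object) {
  if (!object@performed) {
    cat(sprintf("MR-PRESSO: not performed (%s)\n", object@notPerformedReason))
  } else {
    cat(sprintf("MR-PRESSO: global p = %.3g (%d sims), %d outlier(s)\n",
                object@globalPval, object@nSim, length(object@outlierIds)))
    if (length(object@outlierIds))
      cat(sprintf("  outliers: %s; distortion p = %.3g\n",
                  paste(object@outlierIds, collapse = ", "),
                  object@distortionPval))
  }
})

setMethod("show", "LeaveOneOutResult", function(object) {
  cat(sprintf("Leave-one-out over %d instruments; robust = %s\n",
              nrow(object@rows), object@robust))
})

setMethod("show", "SelectionReport", function(object) {
  cat("Instrument selection:\n")
  for (i in seq_len(nrow(object@stages)))
    cat(sprintf("  %-26s %d\n", object@stages$stage[i], object@stages$count[i]))
})

setMethod("show", "MRScenario", function(object) {
  cat(sprintf(
    "MRScenario: theta = %g, J = %d, invalid = %g%% (%s), nExp/nOut = %d/%d, seed = %d\n",
    object@thetaTrue, object@J, 100 * object@invalidFraction,
    object@pleiotropyMode, object@nExp, object@nOut, object@seed))
})

setMethod("show", "PairResult", function(object) {
  cat(sprintf("PairResult: %s (%s, primary p = %.3g, alpha = %g)\n",
              object@exposureName, object@decision, object@primaryPval,
              object@alpha))
  show(object@selection)
  for (est in object@estimates) show(est)
  if (length(object@skipped))
    cat("Skipped:", paste(names(object@skipped), object@skipped,
                          sep = ": ", collapse = "; "), "\n")
})

setMethod("show", "MatrixReport", function(object) {
  cat(sprintf("MatrixReport: %d exposures, %d significant\n",
              length(object@pairs), length(object@significant)))
  if (length(object@significant))
    cat("  significant:", paste(object@significant, collapse = ", "), "\n")
})
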