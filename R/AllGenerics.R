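#' @include AllClasses.R
NULL

#' @rdname SumStats-accessors
#' @export
setGeneric("traitName", function(x) standardGeneric("traitName"))

#' @rdname SumStats-accessors
#' @export
setGeneric("traitType", function(x) standardGeneric("traitType"))

#' @rdname SumStats-accessors
#' @export
setGeneric("variants", function(x) standardGeneric("variants"))

#' @rdname SumStats-accessors
#' @export
setGeneric("nVariants", function(x) standardGeneric("nVariants"))

#' @rdname HarmonizedSet-accessors
#' @export
setGeneric("instruments", function(x) standardGeneric("instruments"))

#' @rdname HarmonizedSet-accessors
#' @export
setGeneric("nInstruments", function(x) standardGeneric("nInstruments"))

#' @rdname HarmonizedSet-accessors
#' @export
setGeneric("exposureName", function(x) standardGeneric("exposureName"))

#' @rdname HarmonizedSet-accessors
#' @export
setGeneric("outcomeName", function(x) standardGeneric("outcomeName"))

#' @rdname mrMetadata
#' @export
setGeneric("mrMetadata", function(x) standardGeneric("mrMetadata"))

#' @rdname selectByPvalue
#' @export
setGeneric("selectByPvalue",
  function(x, threshold = 5e-8) standardGeneric("selectByPvalue"))

#' @rdname ldClump
#' @export
setGeneric("ldClump",
  function(x, ld, r2Threshold = 0.001,
           missingPolicy = c("drop", "keep", "error"))
    standardGeneric("ldClump"))

#' @rdname removePalindromic
#' @export
setGeneric("removePalindromic", function(x) standardGeneric("removePalindromic"))

#' @rdname harmonize
#' @export
setGeneric("harmonize",
  function(exposure, outcome) standardGeneric("harmonize"))

#' @rdname steigerFilter
#' @export
setGeneric("steigerFilter",
  function(x, nExp = NULL, nOut = NULL, r2Method = c("tstat", "eaf"))
    standardGeneric("steigerFilter"))

#' @rdname waldRatio
#' @export
setGeneric("waldRatio",
  function(x, snp = NULL, secondOrder = FALSE) standardGeneric("waldRatio"))

#' @rdname mrIvw
#' @export
setGeneric("mrIvw", function(x) standardGeneric("mrIvw"))

#' @rdname mrEgger
#' @export
setGeneric("mrEgger",
  function(x, forceNullIntercept = FALSE) standardGeneric("mrEgger"))

#' @rdname mrWeightedMedian
#' @export
setGeneric("mrWeightedMedian",
  function(x, nBoot = 1000L, seed) standardGeneric("mrWeightedMedian"))

#' @rdname toOddsRatio
#' @export
setGeneric("toOddsRatio", function(x) standardGeneric("toOddsRatio"))

#' @rdname cochranQ
#' @export
setGeneric("cochranQ",
  function(x, theta, dfReduction = 1L) standardGeneric("cochranQ"))

#' @rdname mrPresso
#' @export
setGeneric("mrPresso",
  function(x, nSim = 1000L, seed, outlierAlpha = 0.05)
    standardGeneric("mrPresso"))

#' @rdname leaveOneOut
#' @export
setGeneric("leaveOneOut", function(x) standardGeneric("leaveOneOut"))

#' @rdname generatePair
#' @export
setGeneric("generatePair", function(scenario) standardGeneric("generatePair"))

#' @rdname runPair
#' @export
setGeneric("runPair",
  function(exposure, outcome, ld, config = mrConfig())
    standardGeneric("runPair"))

#' @rdname runMatrix
#' @export
setGeneric("runMatrix",
  function(exposures, outcome, ld, config = mrConfig())
    standardGeneric("runMatrix"))

#' @rdname renderReports
#' @export
setGeneric("renderReports",
  function(x, outDir) standardGeneric("renderReports"))
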