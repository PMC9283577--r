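#' @include sensitivity.R synthetic.R
NULL

#' Analysis configuration
#'
#' Every threshold of the analysis as a single configuration object. The
#' defaults are the conventional ones for this design: genome-wide
#' significance 5e-8, clumping r-squared 0.001, nominal alpha 0.05 on the
#' primary (IVW) p-value with no multiple-testing adjustment, 1000
#' bootstrap replicates for the weighted median and 1000 simulations for
#' MR-PRESSO.
#'
#' @param pThreshold instrument p-value threshold.
#' @param clumpR2 LD-clumping r-squared threshold.
#' @param alpha decision threshold on the primary p-value.
#' @param nBoot weighted-median bootstrap replicates.
#' @param pressoNSim MR-PRESSO simulation count.
#' @param outlierAlpha MR-PRESSO outlier threshold.
#' @param seed base RNG seed for bootstrap/PRESSO (per-exposure seeds are
#'   derived as `seed + exposure index`).
#' @param adjust multiple-testing adjustment across exposures in
#'   [runMatrix()]: `"none"` (default), `"bonferroni"` or `"BH"`.
#' @param missingLdPolicy passed to [ldClump()].
#' @param steigerR2Method passed to [steigerFilter()].
#' @return a named list of class `mrConfig`.
#' @export
mrConfig <- function(pThreshold = 5e-8, clumpR2 = 0.001, alpha = 0.05,
                     nBoot = 1000L, pressoNSim = 1000L, outlierAlpha = 0.05,
                     seed = 1L, adjust = c("none", "bonferroni", "BH"),
                     missingLdPolicy = c("drop", "keep", "error"),
                     steigerR2Method = c("tstat", "eaf")) {
  cfg <- list(pThreshold = pThreshold, clumpR2 = clumpR2, alpha = alpha,
              nBoot = as.integer(nBoot), pressoNSim = as.integer(pressoNSim),
              outlierAlpha = outlierAlpha, seed = as.integer(seed),
              adjust = match.arg(adjust),
              missingLdPolicy = match.arg(missingLdPolicy),
              steigerR2Method = match.arg(steigerR2Method))
  class(cfg) <- "mrConfig"
  cfg
}

#' Read a configuration file
#'
#' Key-value YAML; unknown keys are rejected, absent keys take defaults.
#'
#' @param path YAML file path.
#' @return an `mrConfig` list.
#' @export
readMrConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(mrConfig))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop(sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  do.call(mrConfig, vals)
}

.newSelectionReport <- function(counts, drops) {
  new("SelectionReport",
      stages = data.frame(stage = names(counts),
                          count = as.integer(unname(counts)),
                          stringsAsFactors = FALSE),
      drops = drops)
}

.noDrops <- function() data.frame(snp = character(), stage = character(),
                                  reason = character(), stringsAsFactors = FALSE)

#' Run the full MR analysis for one exposure-outcome pair
#'
#' Executes the pipeline in order — significance filter, LD clumping,
#' palindrome removal, harmonization against the outcome, Steiger
#' directionality filter — then every estimator and sensitivity analysis
#' the surviving instrument count supports: 1 instrument gives the Wald
#' ratio only; 2 adds IVW; 3 add MR-Egger, the weighted median and
#' leave-one-out; 4 or more add MR-PRESSO. Skipped components are recorded
#' with reasons, never silently absent. The decision is `significant`
#' exactly when the primary p-value (IVW; the algebraically identical Wald
#' ratio when only one instrument survives) is below `config$alpha`.
#'
#' @param exposure,outcome [SumStats-class] objects.
#' @param ld an [LdMatrix-class].
#' @param config an [mrConfig()] list.
#' @return a [PairResult-class]. Zero surviving instruments give a
#'   structured empty result, not an error.
#' @export
setMethod("runPair", signature("SumStats", "SumStats", "LdMatrix"),
  function(exposure, outcome, ld, config = mrConfig()) {
  counts <- c(candidates = nVariants(exposure))
  drops <- .noDrops()
  grab <- function(x) {
    lf <- mrMetadata(x)$lastFilter
    if (!is.null(lf) && nrow(lf$dropped)) drops <<- rbind(drops, lf$dropped)
    x
  }
  s <- grab(selectByPvalue(exposure, config$pThreshold))
  counts["pass_pvalue"] <- nVariants(s)
  s <- grab(suppressWarnings(
    ldClump(s, ld, config$clumpR2, missingPolicy = config$missingLdPolicy)))
  counts["pass_clump"] <- nVariants(s)
  s <- grab(removePalindromic(s))
  counts["pass_palindrome"] <- nVariants(s)
  h <- harmonize(s, outcome)
  hd <- mrMetadata(h)$dropped
  if (!is.null(hd) && nrow(hd))
    drops <- rbind(drops, data.frame(snp = hd$snp,
                                     stage = "pass_overlap_with_outcome",
                                     reason = hd$reason))
  counts["pass_overlap_with_outcome"] <- nInstruments(h)
  h <- tryCatch(grab(steigerFilter(h, r2Method = config$steigerR2Method)),
                error = function(e) h)
  counts["pass_steiger"] <- nInstruments(h)
  selection <- .newSelectionReport(counts, drops)

  J <- nInstruments(h)
  estimates <- list()
  heterogeneity <- list()
  presso <- NULL
  loo <- NULL
  skipped <- character()
  if (J >= 1) {
    if (J == 1) estimates$wald <- waldRatio(h)
    else skipped["wald"] <- "reported_via_ivw_with_multiple_instruments"
  } else skipped["wald"] <- "no_instruments"
  if (J >= 2) {
    fit <- mrIvw(h)
    estimates$ivw <- fit$estimate
    heterogeneity$ivw <- fit$heterogeneity
  } else skipped["ivw"] <- "fewer_than_2_instruments"
  if (J >= 3) {
    eg <- mrEgger(h)
    estimates$egger_slope <- eg$slope
    estimates$egger_intercept <- eg$intercept
    heterogeneity$egger <- eg$heterogeneity
    estimates$weighted_median <-
      mrWeightedMedian(h, nBoot = config$nBoot, seed = config$seed)
    loo <- leaveOneOut(h)
  } else {
    skipped["egger"] <- "fewer_than_3_instruments"
    skipped["weighted_median"] <- "fewer_than_3_instruments"
    skipped["leave_one_out"] <- "fewer_than_3_instruments"
  }
  if (J >= 1) {
    presso <- mrPresso(h, nSim = config$pressoNSim, seed = config$seed,
                       outlierAlpha = config$outlierAlpha)
    if (!presso@performed) skipped["presso"] <- presso@notPerformedReason
  } else skipped["presso"] <- "no_instruments"

  primaryPval <- if (!is.null(estimates$ivw)) estimates$ivw@pval
    else if (!is.null(estimates$wald)) estimates$wald@pval
    else NA_real_
  decision <- if (is.finite(primaryPval) && primaryPval < config$alpha)
    "significant" else "not_significant"
  new("PairResult", exposureName = traitName(exposure),
      selection = selection, instruments = h, estimates = estimates,
      heterogeneity = heterogeneity, presso = presso, leaveOneOut = loo,
      skipped = skipped, decision = decision, alpha = config$alpha,
      primaryPval = primaryPval)
})

#' Screen many exposures against one outcome
#'
#' Runs [runPair()] per exposure with a per-exposure derived seed
#' (`config$seed + index`) and aggregates the results. By default decisions
#' use the nominal alpha with no multiple-testing adjustment;
#' `config$adjust` switches to Bonferroni or Benjamini-Hochberg adjusted
#' primary p-values.
#'
#' @param exposures named list of [SumStats-class] objects (names default
#'   to each trait's name).
#' @param outcome a [SumStats-class].
#' @param ld an [LdMatrix-class].
#' @param config an [mrConfig()] list.
#' @return a [MatrixReport-class].
#' @export
setMethod("runMatrix", signature("list", "SumStats", "LdMatrix"),
  function(exposures, outcome, ld, config = mrConfig()) {
  if (!length(exposures))
    stop("at least one exposure is required", call. = FALSE)
  if (is.null(names(exposures)) || any(names(exposures) == ""))
    names(exposures) <- vapply(exposures, traitName, character(1))
  seeds <- config$seed + seq_along(exposures)
  pairs <- vector("list", length(exposures))
  for (i in seq_along(exposures)) {
    cfg <- config
    cfg$seed <- seeds[i]
    pairs[[i]] <- runPair(exposures[[i]], outcome, ld, cfg)
  }
  names(pairs) <- names(exposures)
  if (config$adjust != "none") {
    praw <- vapply(pairs, function(p) p@primaryPval, numeric(1))
    padj <- stats::p.adjust(praw,
                            method = if (config$adjust == "BH") "BH"
                                     else "bonferroni")
    for (i in seq_along(pairs)) {
      p <- pairs[[i]]
      p@primaryPval <- padj[i]
      p@decision <- if (is.finite(padj[i]) && padj[i] < config$alpha)
        "significant" else "not_significant"
      pairs[[i]] <- p
    }
  }
  sig <- names(pairs)[vapply(pairs, function(p)
    p@decision == "significant", logical(1))]
  totalInstruments <- sum(vapply(pairs, function(p)
    nInstruments(p@instruments), integer(1)))
  new("MatrixReport", pairs = pairs, significant = sig,
      metadata = list(config = unclass(config), seeds = seeds,
                      totalInstruments = totalInstruments,
                      package = as.character(utils::packageVersion("mrflow"))))
})

.fmtP <- function(p) ifelse(is.na(p), "NA", signif(p, 3))
.fmt2 <- function(x) ifelse(is.na(x), "NA", sprintf("%.2f", x))

#' Render report tables for a screen
#'
#' Writes tab-separated report tables: per-method estimates (instrument
#' count, odds ratio and 95% CI rounded to two decimals, p-value to three
#' significant figures), sensitivity results (Q statistics and Egger
#' intercepts), MR-PRESSO results, leave-one-out rows, the selection-stage
#' accounting with per-variant drop reasons, the significant subset, and a
#' YAML run-metadata file sufficient to re-run the screen.
#'
#' @param x a [MatrixReport-class].
#' @param outDir output directory (created if needed).
#' @return character vector of written file paths, invisibly.
#' @export
setMethod("renderReports", "MatrixReport", function(x, outDir) {
  ok <- dir.exists(outDir) || dir.create(outDir, recursive = TRUE,
                                         showWarnings = FALSE)
  if (!ok || file.access(outDir, 2) != 0)
    stop(sprintf("cannot write to directory '%s'", outDir), call. = FALSE)
  wt <- function(d, file) {
    path <- file.path(outDir, file)
    utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
    path
  }
  methodLabel <- c(wald = "Wald", ivw = "IVW", egger_slope = "MR Egger",
                   egger_intercept = "MR Egger intercept",
                   weighted_median = "WM")

  est <- list(); sens <- list(); pres <- list(); loo <- list()
  sel <- list(); drops <- list()
  for (nm in names(x@pairs)) {
    p <- x@pairs[[nm]]
    for (key in names(p@estimates)) {
      e <- p@estimates[[key]]
      orr <- toOddsRatio(e)
      est[[length(est) + 1L]] <- data.frame(
        exposure = nm, method = methodLabel[[key]], n_snp = e@nSnp,
        OR = .fmt2(orr@or), ci_low = .fmt2(orr@orLow),
        ci_high = .fmt2(orr@orHigh), pval = .fmtP(e@pval),
        stringsAsFactors = FALSE)
    }
    for (key in names(p@heterogeneity)) {
      q <- p@heterogeneity[[key]]
      int <- p@estimates$egger_intercept
      sens[[length(sens) + 1L]] <- data.frame(
        exposure = nm, method = if (key == "ivw") "IVW" else "MR Egger",
        Q = .fmt2(q@Q), Q_pval = .fmtP(q@pval),
        egger_intercept = if (key == "ivw" && !is.null(int))
          sprintf("%.3f", int@theta) else "",
        intercept_pval = if (key == "ivw" && !is.null(int))
          .fmtP(int@pval) else "",
        stringsAsFactors = FALSE)
    }
    pr <- p@presso
    pres[[length(pres) + 1L]] <- data.frame(
      exposure = nm,
      performed = if (is.null(pr)) FALSE else pr@performed,
      global_pval = if (!is.null(pr) && pr@performed) .fmtP(pr@globalPval) else "NA",
      outliers = if (!is.null(pr) && pr@performed)
        paste(pr@outlierIds, collapse = ",") else "",
      distortion_pval = if (!is.null(pr) && pr@performed)
        .fmtP(pr@distortionPval) else "NA",
      reason = if (!is.null(pr) && !pr@performed) pr@notPerformedReason else "",
      stringsAsFactors = FALSE)
    if (!is.null(p@leaveOneOut)) {
      r <- p@leaveOneOut@rows
      loo[[length(loo) + 1L]] <- data.frame(
        exposure = nm, snp = r$snp, theta = sprintf("%.6g", r$theta),
        se = sprintf("%.6g", r$se), pval = .fmtP(r$pval),
        stringsAsFactors = FALSE)
    }
    sel[[length(sel) + 1L]] <- data.frame(
      exposure = nm, stage = p@selection@stages$stage,
      count = p@selection@stages$count, stringsAsFactors = FALSE)
    if (nrow(p@selection@drops))
      drops[[length(drops) + 1L]] <- cbind(exposure = nm, p@selection@drops)
  }
  bindOr <- function(lst, empty) if (length(lst)) do.call(rbind, lst) else empty

  files <- c(
    wt(bindOr(est, data.frame(exposure = character(), method = character(),
                              n_snp = integer(), OR = character(),
                              ci_low = character(), ci_high = character(),
                              pval = character())), "estimates.tsv"),
    wt(bindOr(sens, data.frame(exposure = character(), method = character(),
                               Q = character(), Q_pval = character(),
                               egger_intercept = character(),
                               intercept_pval = character())),
       "sensitivity.tsv"),
    wt(bindOr(pres, data.frame()), "presso.tsv"),
    wt(bindOr(loo, data.frame(exposure = character(), snp = character(),
                              theta = character(), se = character(),
                              pval = character())), "leave_one_out.tsv"),
    wt(bindOr(sel, data.frame(exposure = character(), stage = character(),
                              count = integer())), "selection.tsv"),
    wt(bindOr(drops, data.frame(exposure = character(), snp = character(),
                                stage = character(), reason = character())),
       "selection_drops.tsv"),
    wt(data.frame(exposure = x@significant), "significant.tsv"))
  metaPath <- file.path(outDir, "run_metadata.yaml")
  yaml::write_yaml(x@metadata, metaPath)
  invisible(c(files, metaPath))
})
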