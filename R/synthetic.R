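#' @include accessors.R
NULL

#' Construct a synthetic two-sample GWAS scenario
#'
#' Defines the generative model behind [generatePair()]. True SNP-exposure
#' effects `gamma_j` are drawn from `N(gammaMean, gammaSd)` on a
#' standardized quantitative-trait scale; pleiotropic effects `alpha_j` are
#' zero for valid instruments and drawn from the configured distribution for
#' the invalid fraction (optionally correlated with `gamma_j` to violate
#' the InSIDE assumption). Sampling SEs follow
#' `se = 1/sqrt(2 maf (1-maf) n)` for the exposure and the case-control
#' inflated `se = 1/sqrt(2 maf (1-maf) n phi (1-phi))` (case fraction
#' `phi`) for the binary outcome, mimicking biobank case-control geometry.
#' Defaults reflect the motivating study design: brain-imaging exposures of
#' ~17,700 individuals against a FinnGen-scale glaucoma outcome
#' (8,591 cases / 210,201 controls).
#'
#' @param thetaTrue planted causal effect; default 0.
#' @param J instrument count; default 50.
#' @param invalidFraction fraction of instruments with pleiotropic effects.
#' @param pleiotropyMode `"none"`, `"balanced"` or `"directional"`.
#' @param pleiotropyMean mean pleiotropic effect (directional mode only;
#'   balanced mode forces 0).
#' @param pleiotropySd sd of pleiotropic effects.
#' @param insideViolated correlate `alpha_j` with `gamma_j`.
#' @param insideRho correlation used when `insideViolated` (default 0.8).
#' @param gammaMean,gammaSd SNP-exposure effect distribution; the default
#'   (0.15, 0.02) makes planted instruments reliably genome-wide
#'   significant at the default sample size.
#' @param nExp,nOut per-study sample sizes.
#' @param caseFraction outcome case fraction; default 8591/218792.
#' @param mafRange effect-allele frequency range; default c(0.15, 0.5).
#' @param nNullVariants background variants with zero true effect.
#' @param ldBlockSizes integer block sizes over all variants in order
#'   (instruments first); empty means every variant is independent.
#' @param ldWithinBlockR2 squared correlation within a block; default 0.5.
#' @param palindromicFraction,strandFlipFraction fractions of variants
#'   assigned A/T-C/G allele pairs, resp. complemented outcome-study allele
#'   labels; default 0.
#' @param seed integer RNG seed (required).
#' @return a validated [MRScenario-class] object.
#' @export
MRScenario <- function(thetaTrue = 0, J = 50L, invalidFraction = 0,
                       pleiotropyMode = c("none", "balanced", "directional"),
                       pleiotropyMean = 0.02, pleiotropySd = 0.01,
                       insideViolated = FALSE, insideRho = 0.8,
                       gammaMean = 0.15, gammaSd = 0.02,
                       nExp = 17706L, nOut = 218792L,
                       caseFraction = 8591 / 218792,
                       mafRange = c(0.15, 0.5), nNullVariants = 0L,
                       ldBlockSizes = integer(), ldWithinBlockR2 = 0.5,
                       palindromicFraction = 0, strandFlipFraction = 0,
                       seed) {
  pleiotropyMode <- match.arg(pleiotropyMode)
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  if (pleiotropyMode == "balanced") pleiotropyMean <- 0
  new("MRScenario", thetaTrue = thetaTrue, J = as.integer(J),
      invalidFraction = invalidFraction, pleiotropyMode = pleiotropyMode,
      pleiotropyMean = pleiotropyMean, pleiotropySd = pleiotropySd,
      insideViolated = insideViolated, insideRho = insideRho,
      gammaMean = gammaMean, gammaSd = gammaSd, nExp = as.integer(nExp),
      nOut = as.integer(nOut), caseFraction = caseFraction,
      mafRange = as.numeric(mafRange), nNullVariants = as.integer(nNullVariants),
      ldBlockSizes = as.integer(ldBlockSizes),
      ldWithinBlockR2 = ldWithinBlockR2,
      palindromicFraction = palindromicFraction,
      strandFlipFraction = strandFlipFraction, seed = as.integer(seed))
}

## Non-palindromic ordered allele pairs.
.NONPAL_PAIRS <- {
  p <- expand.grid(ea = .BASES, oa = .BASES, stringsAsFactors = FALSE)
  p <- p[p$ea != p$oa & !.isPalindromic(p$ea, p$oa), ]
  rownames(p) <- NULL
  p
}

#' Generate a synthetic exposure/outcome summary-statistic pair
#'
#' Draws one realisation of the scenario's generative model and returns
#' exposure and outcome summary-statistic tables (same on-disk dialect as
#' [readSumStats()]), a block-diagonal LD matrix over all variants, and a
#' per-variant truth record. Observed effects are
#' `beta_exp_j ~ N(gamma_j, se_exp_j)` and
#' `beta_out_j ~ N(thetaTrue * gamma_j + alpha_j, se_out_j)`; p-values come
#' from the observed z-statistics; background null variants have
#' `gamma = 0`. Identical scenarios (including seed) give identical output.
#'
#' @param scenario an [MRScenario-class].
#' @return list with elements `exposure`, `outcome` ([SumStats-class]),
#'   `ld` ([LdMatrix-class]) and `truth` (data.frame `snp`, `gamma`,
#'   `alpha`, `maf`, `instrument`, `valid`).
#' @export
#' @examples
#' pair <- generatePair(MRScenario(thetaTrue = 0.5, J = 10, seed = 1))
#' head(pair$truth)
setMethod("generatePair", "MRScenario", function(scenario) {
  s <- scenario
  total <- s@J + s@nNullVariants
  if (length(s@ldBlockSizes) && sum(s@ldBlockSizes) != total)
    stop("ldBlockSizes inconsistent with variant count", call. = FALSE)
  .withSeed(s@seed, {
    ids <- sprintf("rs%05d", seq_len(total))
    maf <- stats::runif(total, s@mafRange[1], s@mafRange[2])
    isInstr <- seq_len(total) <= s@J
    gamma <- numeric(total)
    gamma[isInstr] <- stats::rnorm(s@J, s@gammaMean, s@gammaSd)

    # invalid-instrument bookkeeping: round half-up of invalidFraction * J
    nInvalid <- floor(s@invalidFraction * s@J + 0.5)
    invalid <- rep(FALSE, total)
    if (nInvalid > 0 && s@pleiotropyMode != "none")
      invalid[sample.int(s@J, nInvalid)] <- TRUE
    alpha <- numeric(total)
    if (any(invalid)) {
      eps <- stats::rnorm(sum(invalid))
      if (s@insideViolated && s@gammaSd > 0) {
        zg <- (gamma[invalid] - s@gammaMean) / s@gammaSd
        eps <- s@insideRho * zg + sqrt(1 - s@insideRho^2) * eps
      }
      alpha[invalid] <- s@pleiotropyMean + s@pleiotropySd * eps
    }

    seExp <- 1 / sqrt(2 * maf * (1 - maf) * s@nExp)
    seOut <- 1 / sqrt(2 * maf * (1 - maf) * s@nOut *
                        s@caseFraction * (1 - s@caseFraction))
    betaExp <- stats::rnorm(total, gamma, seExp)
    betaOut <- stats::rnorm(total, s@thetaTrue * gamma + alpha, seOut)

    # allele labels: non-palindromic by default, with configured fractions
    # of palindromic pairs and of strand-complemented outcome labels
    pairIdx <- sample.int(nrow(.NONPAL_PAIRS), total, replace = TRUE)
    ea <- .NONPAL_PAIRS$ea[pairIdx]
    oa <- .NONPAL_PAIRS$oa[pairIdx]
    if (s@palindromicFraction > 0) {
      nPal <- floor(s@palindromicFraction * total + 0.5)
      if (nPal > 0) {
        palIdx <- sample.int(total, nPal)
        palEa <- sample(.BASES, nPal, replace = TRUE)
        ea[palIdx] <- palEa
        oa[palIdx] <- .complement(palEa)
      }
    }
    eaOut <- ea; oaOut <- oa
    if (s@strandFlipFraction > 0) {
      nFlip <- floor(s@strandFlipFraction * total + 0.5)
      if (nFlip > 0) {
        flipIdx <- sample.int(total, nFlip)
        flippable <- flipIdx[!.isPalindromic(ea[flipIdx], oa[flipIdx])]
        eaOut[flippable] <- .complement(ea[flippable])
        oaOut[flippable] <- .complement(oa[flippable])
      }
    }

    base <- data.frame(snp = ids, chr = "1",
                       pos = seq_len(total) * 10000L,
                       eaf = maf, stringsAsFactors = FALSE)
    expTab <- base
    expTab$ea <- ea; expTab$oa <- oa
    expTab$beta <- betaExp; expTab$se <- seExp
    expTab$pval <- .pNorm2(betaExp / seExp); expTab$n <- s@nExp
    outTab <- base
    outTab$ea <- eaOut; outTab$oa <- oaOut
    outTab$beta <- betaOut; outTab$se <- seOut
    outTab$pval <- .pNorm2(betaOut / seOut); outTab$n <- s@nOut

    blocks <- if (length(s@ldBlockSizes)) s@ldBlockSizes else rep(1L, total)
    r2 <- diag(1, total)
    at <- 0L
    for (b in blocks) {
      idx <- at + seq_len(b)
      r2[idx, idx] <- s@ldWithinBlockR2
      at <- at + b
    }
    diag(r2) <- 1
    dimnames(r2) <- list(ids, ids)

    truth <- data.frame(snp = ids, gamma = gamma, alpha = alpha, maf = maf,
                        instrument = isInstr,
                        valid = isInstr & !invalid, stringsAsFactors = FALSE)
    list(exposure = SumStats(expTab, traitName = "synthetic_exposure",
                             traitType = "quantitative"),
         outcome = SumStats(outTab, traitName = "synthetic_outcome",
                            traitType = "binary"),
         ld = LdMatrix(r2),
         truth = truth)
  })
})

#' Named scenario presets
#'
#' A collection of ready-made scenarios covering the regimes the package's
#' calibration studies use: a null model, a valid causal model, balanced
#' and directional pleiotropy, an InSIDE-violating scenario, a 3-instrument
#' scenario (on which MR-PRESSO returns a structured not-performed result),
#' a weak-instrument regime, and a full screen scenario with background
#' null variants, LD blocks, palindromes and strand flips for exercising
#' the selection pipeline end to end.
#'
#' @param seed base RNG seed stored in every preset (default 1).
#' @return named list of [MRScenario-class] objects with elements
#'   `null_model`, `valid_causal`, `balanced_pleiotropy`,
#'   `directional_pleiotropy`, `inside_violated`, `few_snps_3`,
#'   `many_weak`, `screen_demo`.
#' @export
scenarioPresets <- function(seed = 1L) {
  list(
    null_model = MRScenario(thetaTrue = 0, J = 20L, nExp = 20000L,
                            nOut = 20000L, seed = seed),
    valid_causal = MRScenario(thetaTrue = 0.5, J = 50L, nExp = 20000L,
                              nOut = 20000L, seed = seed),
    balanced_pleiotropy = MRScenario(thetaTrue = 0.5, J = 50L,
                                     invalidFraction = 0.3,
                                     pleiotropyMode = "balanced",
                                     pleiotropySd = 0.02, nExp = 20000L,
                                     nOut = 20000L, seed = seed),
    # strong instruments against a large balanced case-control outcome, so
    # the ratio noise (~0.03) is small relative to the pleiotropy shift
    # (~0.5): the regime where the weighted median's breakdown is visible
    directional_pleiotropy = MRScenario(thetaTrue = 0.5, J = 50L,
                                        invalidFraction = 0.3,
                                        pleiotropyMode = "directional",
                                        pleiotropyMean = 0.075,
                                        pleiotropySd = 0.01,
                                        gammaMean = 0.15, gammaSd = 0.01,
                                        nExp = 100000L, nOut = 600000L,
                                        caseFraction = 0.5,
                                        mafRange = c(0.3, 0.5), seed = seed),
    inside_violated = MRScenario(thetaTrue = 0.5, J = 50L,
                                 invalidFraction = 0.3,
                                 pleiotropyMode = "directional",
                                 pleiotropyMean = 0.02, pleiotropySd = 0.01,
                                 insideViolated = TRUE, nExp = 20000L,
                                 nOut = 20000L, seed = seed),
    few_snps_3 = MRScenario(thetaTrue = 0.5, J = 3L, nExp = 20000L,
                            nOut = 20000L, seed = seed),
    many_weak = MRScenario(thetaTrue = 0.5, J = 100L, gammaMean = 0.02,
                           gammaSd = 0.005, nExp = 20000L, nOut = 20000L,
                           seed = seed),
    screen_demo = MRScenario(thetaTrue = 0.5, J = 30L, nExp = 20000L,
                             nOut = 20000L, nNullVariants = 470L,
                             ldBlockSizes = c(rep(1L, 30L), rep(10L, 47L)),
                             ldWithinBlockR2 = 0.6,
                             palindromicFraction = 0.1,
                             strandFlipFraction = 0.1, seed = seed))
}
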