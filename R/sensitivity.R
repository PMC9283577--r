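#' @include estimators.R
NULL

#' Cochran's Q heterogeneity test
#'
#' Weighted dispersion of the per-variant Wald ratios around a causal
#' estimate: `Q = sum w'_j (theta_j - theta)^2` with first-order ratio
#' weights `w'_j = beta_exp_j^2/se_out_j^2` (algebraically
#' `sum (beta_out_j - theta beta_exp_j)^2 / se_out_j^2`). Under homogeneity
#' Q follows a chi-square distribution with `J - dfReduction` degrees of
#' freedom (`dfReduction` 1 for the IVW fit, 2 for Egger).
#'
#' @param x a [HarmonizedSet-class].
#' @param theta causal estimate the ratios are compared against.
#' @param dfReduction parameters absorbed by the fitted model (default 1).
#' @return a [HeterogeneityResult-class].
#' @export
setMethod("cochranQ", "HarmonizedSet",
  function(x, theta, dfReduction = 1L) {
  d <- instruments(x)
  J <- nrow(d)
  dfReduction <- as.integer(dfReduction)
  if (J <= dfReduction)
    stop(sprintf("Cochran's Q needs more than %d instruments", dfReduction),
         call. = FALSE)
  .assertScalarNumber(theta, "theta")
  Q <- sum((d$beta_out - theta * d$beta_exp)^2 / d$se_out^2)
  .newHeterogeneity(if (dfReduction == 1L) "ivw" else "egger", Q,
                    J - dfReduction)
})

## Leave-one-out IVW point estimates via totals-minus-one, vectorized over
## instruments (and, matrix-shaped, over simulated datasets in MR-PRESSO).
.looTheta <- function(bx, by, w) {
  s1 <- sum(w * bx * by)
  s2 <- sum(w * bx^2)
  (s1 - w * bx * by) / (s2 - w * bx^2)
}

#' MR-PRESSO: pleiotropy residual sum and outlier test
#'
#' Simulation-based detection of pleiotropic outlier instruments. With
#' fewer than 4 instruments the test cannot be performed and a structured
#' not-performed result is returned. Otherwise:
#'
#' 1. For each variant the leave-one-out IVW estimate gives an expected
#'    outcome effect; the observed residual sum is
#'    `RSS_obs = sum_j w_j (beta_out_j - theta_{-j} beta_exp_j)^2`,
#'    `w_j = 1/se_out_j^2`.
#' 2. `nSim` datasets are simulated under the no-pleiotropy null
#'    (`beta_out*_j ~ N(theta_{-j} beta_exp_j, se_out_j)`,
#'    `beta_exp*_j ~ N(beta_exp_j, se_exp_j)`) and RSS recomputed for each;
#'    the global p is the add-one-smoothed exceedance fraction.
#' 3. Each variant's observed weighted squared residual is compared with
#'    its simulated distribution; the empirical p-values are Bonferroni
#'    multiplied by J and variants below `outlierAlpha` flagged.
#' 4. When outliers are flagged, the outlier-corrected IVW estimate is
#'    computed on the remainder, and the distortion p-value compares the
#'    raw-minus-corrected difference with differences obtained by removing
#'    random outlier-sized subsets.
#'
#' @param x a [HarmonizedSet-class].
#' @param nSim simulated null datasets (>= 100; default 1000).
#' @param seed integer RNG seed (required).
#' @param outlierAlpha threshold on the Bonferroni-adjusted outlier p-values
#'   (default 0.05).
#' @return a [PressoResult-class].
#' @export
setMethod("mrPresso", "HarmonizedSet",
  function(x, nSim = 1000L, seed, outlierAlpha = 0.05) {
  d <- instruments(x)
  J <- nrow(d)
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  seed <- as.integer(seed)
  nSim <- as.integer(nSim)
  if (nSim < 100L) stop("'nSim' must be >= 100", call. = FALSE)
  if (J < 4) {
    return(new("PressoResult", performed = FALSE, rssObs = NA_real_,
               globalPval = NA_real_, outlierIds = character(),
               outlierPvals = numeric(), distortionPval = NA_real_,
               thetaRaw = NA_real_, thetaCorrected = NA_real_,
               nSim = nSim, seed = seed,
               notPerformedReason = "insufficient_snps"))
  }
  bx <- d$beta_exp; by <- d$beta_out
  sx <- d$se_exp; sy <- d$se_out
  w <- 1 / sy^2
  thetaLoo <- .looTheta(bx, by, w)
  resObs <- w * (by - thetaLoo * bx)^2
  rssObs <- sum(resObs)
  thetaRaw <- .ivw(bx, by, sy)$theta

  sim <- .withSeed(seed, {
    bxS <- matrix(stats::rnorm(J * nSim, bx, sx), nrow = J)
    byS <- matrix(stats::rnorm(J * nSim, thetaLoo * bx, sy), nrow = J)
    s1 <- colSums(w * bxS * byS)
    s2 <- colSums(w * bxS^2)
    thetaLooS <- (rep(s1, each = J) - w * bxS * byS) /
      (rep(s2, each = J) - w * bxS^2)
    resS <- w * (byS - thetaLooS * bxS)^2              # J x nSim
    list(rss = colSums(resS), res = resS)
  })
  globalPval <- (1 + sum(sim$rss >= rssObs)) / (1 + nSim)
  pOut <- (1 + rowSums(sim$res >= resObs)) / (1 + nSim)
  pOutAdj <- pmin(1, pOut * J)
  names(pOutAdj) <- d$snp
  flagged <- d$snp[pOutAdj < outlierAlpha]

  if (length(flagged) && length(flagged) <= J - 2) {
    keep <- !(d$snp %in% flagged)
    thetaCorrected <- .ivw(bx[keep], by[keep], sy[keep])$theta
    dObs <- thetaRaw - thetaCorrected
    dSim <- .withSeed(seed + 1L, {
      vapply(seq_len(nSim), function(i) {
        drop <- sample.int(J, length(flagged))
        thetaRaw - .ivw(bx[-drop], by[-drop], sy[-drop])$theta
      }, numeric(1))
    })
    distortionPval <- (1 + sum(abs(dSim) >= abs(dObs))) / (1 + nSim)
  } else {
    thetaCorrected <- thetaRaw
    distortionPval <- NA_real_
  }
  new("PressoResult", performed = TRUE, rssObs = rssObs,
      globalPval = globalPval, outlierIds = flagged, outlierPvals = pOutAdj,
      distortionPval = distortionPval, thetaRaw = thetaRaw,
      thetaCorrected = thetaCorrected, nSim = nSim, seed = seed,
      notPerformedReason = NA_character_)
})

#' Leave-one-out robustness analysis
#'
#' Re-estimates the multiplicative random-effects IVW causal effect with
#' each instrument removed in turn. The robustness flag is TRUE when every
#' leave-one-out CI agrees with the full-set CI on whether zero is
#' excluded — i.e. no single instrument drives the conclusion.
#'
#' @param x a [HarmonizedSet-class] with at least 3 instruments.
#' @return a [LeaveOneOutResult-class].
#' @export
setMethod("leaveOneOut", "HarmonizedSet", function(x) {
  d <- instruments(x)
  J <- nrow(d)
  if (J < 3) stop("leave-one-out needs at least 3 instruments", call. = FALSE)
  full <- mrIvw(x)$estimate
  rows <- do.call(rbind, lapply(seq_len(J), function(j) {
    fit <- .ivw(d$beta_exp[-j], d$beta_out[-j], d$se_out[-j])
    data.frame(snp = d$snp[j], theta = fit$theta, se = fit$se,
               ciLow = fit$theta - .Z95 * fit$se,
               ciHigh = fit$theta + .Z95 * fit$se,
               pval = fit$pval, stringsAsFactors = FALSE)
  }))
  excludesZero <- function(lo, hi) lo > 0 | hi < 0
  robust <- all(excludesZero(rows$ciLow, rows$ciHigh)) ==
    excludesZero(full@ciLow, full@ciHigh)
  new("LeaveOneOutResult", rows = rows, full = full, robust = robust)
})
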