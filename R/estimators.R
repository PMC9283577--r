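#' @include accessors.R
NULL

## Core causal estimators. All work on the harmonized per-variant summary
## statistics (beta_exp, se_exp, beta_out, se_out); internal .ivw/.wls
## helpers operate on bare vectors so sensitivity analyses and simulations
## can reuse them without container overhead.

## Through-origin weighted least squares with multiplicative random-effects
## SE: weights 1/se_out^2, overdispersion multiplier floored at 1.
.ivw <- function(bx, by, sy) {
  J <- length(bx)
  w <- 1 / sy^2
  S2 <- sum(w * bx^2)
  theta <- sum(w * bx * by) / S2
  Q <- sum(w * (by - theta * bx)^2)
  phi <- if (J > 1) max(1, sqrt(Q / (J - 1))) else 1
  se <- sqrt(1 / S2) * phi
  list(theta = theta, se = se, Q = Q, phi = phi,
       pval = .pNorm2(theta / se))
}

#' Wald ratio for a single instrument
#'
#' Per-variant causal estimate: the SNP-outcome effect divided by the
#' SNP-exposure effect, with the first-order standard error
#' `se_out / |beta_exp|`. With `secondOrder = TRUE` the exposure
#' uncertainty is propagated:
#' `se = sqrt(se_out^2 / beta_exp^2 + beta_out^2 se_exp^2 / beta_exp^4)`.
#'
#' @param x a [HarmonizedSet-class].
#' @param snp variant ID to use; may be omitted when the set holds exactly
#'   one instrument.
#' @param secondOrder propagate exposure-side uncertainty into the SE.
#' @return a [CausalEstimate-class] (`method = "wald"`).
#' @export
setMethod("waldRatio", "HarmonizedSet",
  function(x, snp = NULL, secondOrder = FALSE) {
  d <- instruments(x)
  if (is.null(snp)) {
    if (nrow(d) != 1L)
      stop("'snp' must be given when the set holds more than one instrument",
           call. = FALSE)
    row <- d
  } else {
    row <- d[d$snp == snp, , drop = FALSE]
    if (nrow(row) != 1L) stop(sprintf("unknown variant '%s'", snp), call. = FALSE)
  }
  if (row$beta_exp == 0)
    stop("Wald ratio undefined: beta_exp is zero", call. = FALSE)
  theta <- row$beta_out / row$beta_exp
  se <- if (secondOrder) {
    sqrt(row$se_out^2 / row$beta_exp^2 +
           row$beta_out^2 * row$se_exp^2 / row$beta_exp^4)
  } else {
    row$se_out / abs(row$beta_exp)
  }
  .newEstimate("wald", theta, se, .pNorm2(theta / se), 1L)
})

#' Multiplicative random-effects IVW estimator
#'
#' The primary causal estimator: weighted least squares of the outcome
#' effects on the exposure effects through the origin, weights
#' `1/se_out^2`. Equivalently, the inverse-variance-weighted mean of the
#' per-variant Wald ratios with first-order weights
#' `beta_exp^2/se_out^2`. The multiplicative random-effects SE inflates the
#' fixed-effect SE by `max(1, sqrt(Q/(J-1)))`, where Q is Cochran's
#' heterogeneity statistic, so overdispersion widens the interval but
#' underdispersion never narrows it. P-value from the standard normal; 95%
#' CI at z = 1.959964.
#'
#' @param x a [HarmonizedSet-class] with at least 2 instruments.
#' @return list with elements `estimate` ([CausalEstimate-class],
#'   `method = "ivw_mre"`) and `heterogeneity`
#'   ([HeterogeneityResult-class], df J-1).
#' @export
setMethod("mrIvw", "HarmonizedSet", function(x) {
  d <- instruments(x)
  J <- nrow(d)
  if (J < 2) stop("IVW needs at least 2 instruments", call. = FALSE)
  fit <- .ivw(d$beta_exp, d$beta_out, d$se_out)
  list(estimate = .newEstimate("ivw_mre", fit$theta, fit$se, fit$pval, J,
                               scaleFactor = fit$phi),
       heterogeneity = .newHeterogeneity("ivw", fit$Q, J - 1L))
})

## Weighted linear regression with intercept by explicit normal equations.
.wlsLine <- function(bx, by, w) {
  sw <- sum(w); sx <- sum(w * bx); sxx <- sum(w * bx^2)
  sy <- sum(w * by); sxy <- sum(w * bx * by)
  den <- sw * sxx - sx^2
  if (abs(den) <= .Machine$double.eps * sw * sxx)
    stop("collinear design: all exposure effects equal after orientation",
         call. = FALSE)
  slope <- (sw * sxy - sx * sy) / den
  intercept <- (sxx * sy - sx * sxy) / den
  list(slope = slope, intercept = intercept,
       varSlope = sw / den, varIntercept = sxx / den,
       resid = by - intercept - slope * bx)
}

#' MR-Egger regression
#'
#' Weighted regression of outcome effects on exposure effects with an
#' unconstrained intercept (weights `1/se_out^2`), after orienting every
#' instrument so its exposure effect is non-negative. The slope is the
#' pleiotropy-adjusted causal estimate; the intercept estimates average
#' directional pleiotropy and should be near zero when the exclusion
#' restriction holds (under the InSIDE assumption). SEs carry the estimated
#' residual dispersion `sqrt(Q'/(J-2))` (Q' the Egger residual
#' heterogeneity), exactly as in weighted least squares, and p-values use
#' the t distribution with J-2 degrees of freedom — together this makes the
#' intercept test an exact t-test under homogeneity. (The IVW estimator, by
#' contrast, floors its multiplicative random-effects multiplier at 1; see
#' the methods vignette for the rationale.)
#'
#' @param x a [HarmonizedSet-class] with at least 3 instruments.
#' @param forceNullIntercept fit through the origin instead (then the slope
#'   reproduces the IVW estimate algebraically; used for diagnostics).
#' @return list with elements `slope`, `intercept` (both
#'   [CausalEstimate-class]) and `heterogeneity`
#'   ([HeterogeneityResult-class], df J-2). With `forceNullIntercept` the
#'   `intercept` element is NULL and heterogeneity has df J-1.
#' @export
setMethod("mrEgger", "HarmonizedSet", function(x, forceNullIntercept = FALSE) {
  d <- instruments(x)
  J <- nrow(d)
  if (J < 3) stop("MR-Egger needs at least 3 instruments", call. = FALSE)
  flip <- d$beta_exp < 0
  bx <- ifelse(flip, -d$beta_exp, d$beta_exp)
  by <- ifelse(flip, -d$beta_out, d$beta_out)
  w <- 1 / d$se_out^2
  if (forceNullIntercept) {
    fit <- .ivw(bx, by, d$se_out)
    return(list(slope = .newEstimate("egger_slope", fit$theta, fit$se,
                                     .pT2(fit$theta / fit$se, J - 1L), J,
                                     scaleFactor = fit$phi),
                intercept = NULL,
                heterogeneity = .newHeterogeneity("egger", fit$Q, J - 1L)))
  }
  fit <- .wlsLine(bx, by, w)
  Qp <- sum(w * fit$resid^2)
  # estimated dispersion, not floored (plain WLS); tiny floor keeps SEs
  # positive on numerically perfect fits
  phi <- max(sqrt(Qp / (J - 2)), sqrt(.Machine$double.eps))
  seSlope <- sqrt(fit$varSlope) * phi
  seInt <- sqrt(fit$varIntercept) * phi
  list(
    slope = .newEstimate("egger_slope", fit$slope, seSlope,
                         .pT2(fit$slope / seSlope, J - 2L), J,
                         scaleFactor = phi),
    intercept = .newEstimate("egger_intercept", fit$intercept, seInt,
                             .pT2(fit$intercept / seInt, J - 2L), J,
                             scaleFactor = phi),
    heterogeneity = .newHeterogeneity("egger", Qp, J - 2L))
})

## Weighted-median point estimate on bare vectors (reused by the bootstrap).
## Weights are normalized; ratios sorted; the estimate sits where the
## centred cumulative weight p_j = s_j - w_j/2 crosses 1/2, with linear
## interpolation between the bracketing ratios.
.weightedMedian <- function(ratios, weights) {
  ord <- order(ratios)
  r <- ratios[ord]
  w <- weights[ord] / sum(weights)
  s <- cumsum(w)
  p <- s - w / 2
  hit <- which(abs(p - 0.5) < 1e-12)
  if (length(hit)) return(r[hit[1]])
  if (p[1] >= 0.5) return(r[1])
  if (p[length(p)] <= 0.5) return(r[length(r)])
  k <- max(which(p < 0.5))
  r[k] + (r[k + 1] - r[k]) * (0.5 - p[k]) / (p[k + 1] - p[k])
}

#' Weighted-median estimator
#'
#' Median of the per-variant Wald ratios, weighted by first-order inverse
#' variances `beta_exp^2/se_out^2`: consistent as long as instruments
#' carrying more than half of the total weight are valid. The standard
#' error comes from a parametric bootstrap — each replicate redraws every
#' `beta_exp` and `beta_out` from normal distributions centred at the
#' observed values with their reported SEs and recomputes the weighted
#' median; the SE is the standard deviation over replicates. The seed is
#' mandatory so results are reproducible.
#'
#' @param x a [HarmonizedSet-class] with at least 3 instruments.
#' @param nBoot bootstrap replicates (>= 100; default 1000).
#' @param seed integer RNG seed (required).
#' @return a [CausalEstimate-class] (`method = "weighted_median"`).
#' @export
setMethod("mrWeightedMedian", "HarmonizedSet",
  function(x, nBoot = 1000L, seed) {
  d <- instruments(x)
  J <- nrow(d)
  if (J < 3) stop("weighted median needs at least 3 instruments", call. = FALSE)
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  nBoot <- as.integer(nBoot)
  if (nBoot < 100L) stop("'nBoot' must be >= 100", call. = FALSE)
  ratios <- d$beta_out / d$beta_exp
  weights <- d$beta_exp^2 / d$se_out^2
  theta <- .weightedMedian(ratios, weights)
  boot <- .withSeed(seed, {
    vapply(seq_len(nBoot), function(i) {
      bx <- stats::rnorm(J, d$beta_exp, d$se_exp)
      by <- stats::rnorm(J, d$beta_out, d$se_out)
      .weightedMedian(by / bx, bx^2 / d$se_out^2)
    }, numeric(1))
  })
  se <- stats::sd(boot)
  .newEstimate("weighted_median", theta, se, .pNorm2(theta / se), J)
})

#' Convert a log-odds estimate to an odds ratio
#'
#' Exponentiates the point estimate and its CI bounds. Valid when the
#' outcome associations are on the log-odds scale (binary outcome). Full
#' precision is retained; table renderers round to 2 decimals.
#'
#' @param x a [CausalEstimate-class].
#' @return an [OddsRatio-class].
#' @export
setMethod("toOddsRatio", "CausalEstimate", function(x) {
  new("OddsRatio", or = exp(x@theta), orLow = exp(x@ciLow),
      orHigh = exp(x@ciHigh), pval = x@pval)
})
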