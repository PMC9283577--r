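# Fixture builders and independent oracles used across the suite.

# HarmonizedSet straight from effect vectors.
makeHS <- function(bx, by, sy, sx = rep(0.01, length(bx)),
                   ids = sprintf("s%d", seq_along(bx))) {
  HarmonizedSet(data.frame(snp = ids, beta_exp = bx, se_exp = sx,
                           beta_out = by, se_out = sy,
                           stringsAsFactors = FALSE))
}

# SumStats from minimal arguments; non-palindromic alleles unless given.
makeSS <- function(ids, pvals, ea = "A", oa = "G", beta = 0.1, se = 0.01,
                   trait = "trait", type = "quantitative", n = 20000) {
  k <- length(ids)
  SumStats(data.frame(snp = ids, chr = "1", pos = seq_len(k),
                      ea = rep_len(ea, k), oa = rep_len(oa, k), eaf = 0.3,
                      beta = rep_len(beta, k), se = rep_len(se, k),
                      pval = pvals, n = n, stringsAsFactors = FALSE),
           traitName = trait, traitType = type)
}

# Independent clumping oracle: walk candidates sorted by (pval, id) and
# keep each variant iff its r2 with every already-kept variant is below
# the threshold (formulated differently from the implementation's
# discard loop, but provably the same rule).
bruteClump <- function(ids, pvals, r2, threshold) {
  ord <- order(pvals, ids)
  kept <- character()
  for (i in ord) {
    if (all(r2[ids[i], kept] < threshold)) kept <- c(kept, ids[i])
  }
  kept
}

# Independent normal-equations WLS oracle (with intercept).
wlsOracle <- function(bx, by, w) {
  X <- cbind(1, bx)
  XtWX <- t(X) %*% (w * X)
  XtWy <- t(X) %*% (w * by)
  beta <- solve(XtWX, XtWy)
  resid <- by - X %*% beta
  df <- length(bx) - 2
  sigma2 <- sum(w * resid^2) / df
  covb <- solve(XtWX) * sigma2
  list(intercept = beta[1], slope = beta[2],
       seIntercept = sqrt(covb[1, 1]), seSlope = sqrt(covb[2, 2]))
}

# Independent through-origin WLS oracle.
ivwOracle <- function(bx, by, sy) {
  w <- 1 / sy^2
  theta <- sum(w * bx * by) / sum(w * bx^2)
  Q <- sum(w * (by - theta * bx)^2)
  J <- length(bx)
  se <- sqrt(1 / sum(w * bx^2)) * max(1, sqrt(Q / (J - 1)))
  list(theta = theta, se = se, Q = Q)
}

# Random harmonized instruments for property-style loops.
randomHS <- function(J, seed) {
  set.seed(seed)
  bx <- rnorm(J, 0.1, 0.05)
  bx[abs(bx) < 0.01] <- 0.01
  sy <- runif(J, 0.01, 0.1)
  by <- rnorm(J, 0.3 * bx, sy)
  makeHS(bx, by, sy, sx = runif(J, 0.005, 0.02))
}

# Bare CausalEstimate for transform tests.
.newEstimateForTest <- function(theta, se, method = "ivw_mre", nSnp = 5L) {
  z <- 1.959964
  methods::new("CausalEstimate", method = method, theta = theta, se = se,
               ciLow = theta - z * se, ciHigh = theta + z * se,
               pval = max(2 * pnorm(-abs(theta / se)), 1e-300),
               nSnp = nSnp, scaleFactor = 1)
}

# Harmonize a generated pair and subset to the planted instruments.
harmonizeTruth <- function(pair) {
  h <- harmonize(pair$exposure, pair$outcome)
  keep <- instruments(h)$snp %in% pair$truth$snp[pair$truth$instrument]
  d <- instruments(h)[keep, , drop = FALSE]
  rownames(d) <- NULL
  HarmonizedSet(d, exposureName = exposureName(h),
                outcomeName = outcomeName(h))
}
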