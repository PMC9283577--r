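test_that("generation is deterministic given the scenario seed", {
  s <- MRScenario(thetaTrue = 0.3, J = 15L, nNullVariants = 10L,
                  palindromicFraction = 0.2, strandFlipFraction = 0.2,
                  seed = 77)
  a <- generatePair(s)
  b <- generatePair(s)
  expect_identical(variants(a$exposure), variants(b$exposure))
  expect_identical(variants(a$outcome), variants(b$outcome))
  expect_identical(a$truth, b$truth)
  expect_identical(a$ld@r2, b$ld@r2)
  # and the RNG state of the session is untouched
  set.seed(1); x <- rnorm(1)
  set.seed(1); invisible(generatePair(s)); y <- rnorm(1)
  expect_identical(x, y)
})

test_that("validity flags partition instruments per the invalid fraction", {
  for (frac in c(0, 0.25, 0.3, 0.5, 1)) {
    pair <- generatePair(MRScenario(J = 10L, invalidFraction = frac,
                                    pleiotropyMode = "directional",
                                    seed = 13))
    tr <- pair$truth[pair$truth$instrument, ]
    expect_identical(sum(!tr$valid), as.integer(floor(frac * 10 + 0.5)))
    expect_true(all(tr$alpha[tr$valid] == 0))
  }
  # background variants are never instruments and have zero effects
  pair <- generatePair(MRScenario(J = 5L, nNullVariants = 20L, seed = 13))
  bg <- pair$truth[!pair$truth$instrument, ]
  expect_identical(nrow(bg), 20L)
  expect_true(all(bg$gamma == 0))
})

test_that("sampling SEs are positive and shrink with sample size", {
  ses <- vapply(c(1e3, 1e4, 1e5), function(n) {
    pair <- generatePair(MRScenario(J = 20L, nExp = as.integer(n),
                                    seed = 5))
    mean(variants(pair$exposure)$se)
  }, numeric(1))
  expect_true(all(ses > 0))
  expect_true(all(diff(ses) < 0))
})

test_that("planted instruments reach genome-wide significance at defaults", {
  pv <- unlist(lapply(1:20, function(r) {
    pair <- generatePair(MRScenario(thetaTrue = 0.5, J = 50L, seed = 900 + r))
    variants(pair$exposure)$pval[pair$truth$instrument]
  }))
  expect_gte(mean(pv < 5e-8), 0.99)
})

test_that("allele geometry honors palindromic and strand-flip fractions", {
  pair <- generatePair(MRScenario(J = 100L, palindromicFraction = 0.2,
                                  strandFlipFraction = 0.3, seed = 8))
  de <- variants(pair$exposure)
  do <- variants(pair$outcome)
  isPal <- (de$ea == "A" & de$oa == "T") | (de$ea == "T" & de$oa == "A") |
    (de$ea == "C" & de$oa == "G") | (de$ea == "G" & de$oa == "C")
  expect_identical(sum(isPal), 20L)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  flipped <- do$ea == unname(comp[de$ea]) & do$oa == unname(comp[de$oa]) &
    !isPal
  expect_gt(sum(flipped), 0L)
  # every non-flipped variant matches the exposure labels
  expect_true(all(flipped | (do$ea == de$ea & do$oa == de$oa)))
})

test_that("the LD matrix is block-diagonal with the configured r2", {
  pair <- generatePair(MRScenario(J = 6L, ldBlockSizes = c(3L, 3L),
                                  ldWithinBlockR2 = 0.4, seed = 2))
  r2 <- pair$ld@r2
  expect_identical(r2[1, 2], 0.4)
  expect_identical(r2[1, 4], 0)
  expect_identical(diag(r2), setNames(rep(1, 6), pair$ld@variantIds))
  expect_error(generatePair(MRScenario(J = 5L, ldBlockSizes = c(3L, 3L),
                                       seed = 2)),
               "ldBlockSizes")
})

test_that("scenario presets cover the documented regimes", {
  ps <- scenarioPresets(seed = 4)
  expect_true(all(c("null_model", "valid_causal", "balanced_pleiotropy",
                    "directional_pleiotropy", "inside_violated",
                    "few_snps_3", "many_weak") %in% names(ps)))
  expect_identical(ps$null_model@thetaTrue, 0)
  nullTruth <- generatePair(ps$null_model)$truth
  expect_true(all(nullTruth$alpha == 0))

  dirTruth <- generatePair(ps$directional_pleiotropy)$truth
  planted <- dirTruth$alpha[dirTruth$instrument & !dirTruth$valid]
  expect_gt(mean(planted), 0)   # configured positive direction

  expect_identical(ps$few_snps_3@J, 3L)
  pair3 <- generatePair(ps$few_snps_3)
  h3 <- harmonize(pair3$exposure, pair3$outcome)
  expect_false(mrPresso(h3, nSim = 100, seed = 1)@performed)
})

test_that("directional pleiotropy shifts the Egger intercept detectably", {
  rej <- function(frac) {
    mean(vapply(1:60, function(r) {
      pair <- generatePair(MRScenario(
        thetaTrue = 0.5, J = 50L, invalidFraction = frac,
        pleiotropyMode = if (frac > 0) "directional" else "none",
        pleiotropyMean = 0.02, nExp = 20000L, nOut = 20000L,
        seed = 2000 + r))
      mrEgger(harmonizeTruth(pair))$intercept@pval < 0.05
    }, logical(1)))
  }
  expect_gt(rej(0.3), rej(0))
})

test_that("InSIDE violation induces the configured strength correlation", {
  pair <- generatePair(MRScenario(thetaTrue = 0.5, J = 200L,
                                  invalidFraction = 1,
                                  pleiotropyMode = "directional",
                                  pleiotropyMean = 0.02, pleiotropySd = 0.01,
                                  insideViolated = TRUE, insideRho = 0.8,
                                  seed = 66))
  tr <- pair$truth[pair$truth$instrument, ]
  expect_gt(cor(tr$alpha, tr$gamma), 0.6)
})
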