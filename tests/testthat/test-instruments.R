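test_that("significance filtering is strict and order-preserving", {
  ss <- makeSS(c("a", "b", "c"), c(1e-9, 5e-8, 1e-7))
  kept <- selectByPvalue(ss, 5e-8)
  expect_identical(variants(kept)$snp, "a")   # boundary value dropped
  expect_identical(mrMetadata(kept)$lastFilter$dropped$snp, c("b", "c"))

  expect_identical(nVariants(selectByPvalue(makeSS(c("a", "b"), c(0.5, 0.5)))),
                   0L)

  shuffled <- makeSS(c("z", "m", "a"), c(1e-10, 1e-9, 1e-12))
  expect_identical(variants(selectByPvalue(shuffled))$snp, c("z", "m", "a"))
})

test_that("the generator's planted instruments survive the p-value filter", {
  pair <- generatePair(MRScenario(thetaTrue = 0.3, J = 30L,
                                  nNullVariants = 970L, nExp = 20000L,
                                  nOut = 20000L, seed = 101))
  kept <- selectByPvalue(pair$exposure, 5e-8)
  planted <- pair$truth$snp[pair$truth$instrument]
  expect_setequal(variants(kept)$snp, planted)
})

test_that("greedy LD clumping keeps the best variant per correlated group", {
  ids <- c("s1", "s2", "s3")
  r2 <- diag(3); dimnames(r2) <- list(ids, ids)
  r2["s1", "s2"] <- r2["s2", "s1"] <- 0.5
  r2["s1", "s3"] <- r2["s3", "s1"] <- 0.0005
  r2["s2", "s3"] <- r2["s3", "s2"] <- 0.4
  ss <- makeSS(ids, c(1e-12, 1e-10, 1e-9))
  kept <- ldClump(ss, LdMatrix(r2), 0.001)
  expect_identical(variants(kept)$snp, c("s1", "s3"))

  # all independent -> everything kept
  ind <- diag(3); dimnames(ind) <- list(ids, ids)
  expect_identical(nVariants(ldClump(ss, LdMatrix(ind), 0.001)), 3L)

  # perfect proxies -> smaller-pval one kept
  two <- diag(2); dimnames(two) <- list(c("a", "b"), c("a", "b"))
  two["a", "b"] <- two["b", "a"] <- 1
  ss2 <- makeSS(c("a", "b"), c(1e-8, 1e-10))
  expect_identical(variants(ldClump(ss2, LdMatrix(two), 0.001))$snp, "b")
})

test_that("clumping matches the brute-force greedy oracle on random instances", {
  for (trial in 1:200) {
    set.seed(trial)
    J <- sample(2:15, 1)
    ids <- sprintf("v%02d", 1:J)
    A <- matrix(runif(J * J), J)
    r2 <- (A + t(A)) / 2
    r2[r2 > 1] <- 1
    diag(r2) <- 1
    dimnames(r2) <- list(ids, ids)
    pv <- 10^-runif(J, 8, 15)
    thr <- runif(1, 0.05, 0.8)
    got <- variants(ldClump(makeSS(ids, pv), LdMatrix(r2), thr))$snp
    expect_identical(got, bruteClump(ids, pv, r2, thr))
    # no surviving pair at or above the threshold
    if (length(got) > 1) {
      sub <- r2[got, got]; diag(sub) <- 0
      expect_lt(max(sub), thr)
    }
  }
})

test_that("variants absent from the LD matrix follow the missing policy", {
  ids <- c("s1", "s2")
  m <- diag(1); dimnames(m) <- list("s1", "s1")
  ss <- makeSS(ids, c(1e-10, 1e-9))
  expect_warning(kept <- ldClump(ss, LdMatrix(m), 0.001), "missing")
  expect_identical(variants(kept)$snp, "s1")
  expect_identical(nVariants(ldClump(ss, LdMatrix(m), 0.001,
                                     missingPolicy = "keep")), 2L)
  expect_error(ldClump(ss, LdMatrix(m), 0.001, missingPolicy = "error"),
               "missing")
})

test_that("palindromic variants are removed unconditionally", {
  ss <- SumStats(data.frame(
    snp = sprintf("s%d", 1:6), chr = "1", pos = 1:6,
    ea = c("A", "C", "A", "G", "T", "C"),
    oa = c("T", "G", "G", "T", "C", "A"),
    eaf = 0.5, beta = 0.1, se = 0.01, pval = 1e-9, n = 1000))
  kept <- removePalindromic(ss)
  expect_identical(variants(kept)$snp, c("s3", "s4", "s5", "s6"))
  drops <- mrMetadata(kept)$lastFilter$dropped
  expect_identical(nrow(drops), 2L)
  expect_true(all(drops$reason == "palindromic_alleles"))
})

test_that("harmonization aligns outcome effects onto the exposure allele", {
  expo <- SumStats(data.frame(snp = c("s1", "s2", "s3", "s4", "s5"),
                              chr = "1", pos = 1:5,
                              ea = "A", oa = "G", eaf = 0.3,
                              beta = 0.1, se = 0.01,
                              pval = c(1e-9, 1e-10, 1e-8, 1e-11, 1e-12),
                              n = 10000), traitName = "exp")
  outc <- SumStats(data.frame(snp = c("s1", "s2", "s3", "s4", "s6"),
                              chr = "1", pos = c(1:4, 9),
                              ea = c("A", "G", "T", "A", "A"),
                              oa = c("G", "A", "C", "C", "G"),
                              eaf = 0.3, beta = 0.05, se = 0.02,
                              pval = 0.01, n = 20000),
                   traitName = "out", traitType = "binary")
  h <- harmonize(expo, outc)
  d <- instruments(h)
  expect_identical(d$snp, c("s2", "s1", "s3"))   # ordered by exposure pval
  expect_identical(d$action[d$snp == "s1"], "kept_as_is")
  expect_identical(d$beta_out[d$snp == "s1"], 0.05)
  expect_identical(d$action[d$snp == "s2"], "flipped")
  expect_identical(d$beta_out[d$snp == "s2"], -0.05)
  # s3: outcome T/C complements to the exposure's A/G
  expect_identical(d$action[d$snp == "s3"], "strand_complemented")
  drops <- mrMetadata(h)$dropped
  expect_setequal(drops$snp, c("s4", "s5"))
  expect_identical(drops$reason[drops$snp == "s4"], "allele_mismatch")
  expect_identical(drops$reason[drops$snp == "s5"], "absent_in_outcome")
})

test_that("strand complements harmonize and the rule is idempotent", {
  expo <- makeSS("s1", 1e-9)                       # A/G, beta 0.1
  outcTC <- SumStats(data.frame(snp = "s1", chr = "1", pos = 1, ea = "T",
                                oa = "C", eaf = 0.3, beta = 0.05, se = 0.02,
                                pval = 0.01, n = 1000),
                     traitName = "out", traitType = "binary")
  h <- harmonize(expo, outcTC)
  expect_identical(instruments(h)$action, "strand_complemented")
  expect_identical(instruments(h)$beta_out, 0.05)

  # complement-swapped: C/T vs A/G -> complement then flip
  outcCT <- SumStats(data.frame(snp = "s1", chr = "1", pos = 1, ea = "C",
                                oa = "T", eaf = 0.3, beta = 0.05, se = 0.02,
                                pval = 0.01, n = 1000),
                     traitName = "out", traitType = "binary")
  h2 <- harmonize(expo, outcCT)
  expect_identical(instruments(h2)$beta_out, -0.05)

  # idempotence: re-expressing the harmonized outcome on the exposure
  # alleles and harmonizing again changes nothing
  aligned <- SumStats(data.frame(snp = "s1", chr = "1", pos = 1, ea = "A",
                                 oa = "G", eaf = 0.3,
                                 beta = instruments(h)$beta_out, se = 0.02,
                                 pval = 0.01, n = 1000),
                      traitName = "out", traitType = "binary")
  h3 <- harmonize(expo, aligned)
  expect_identical(instruments(h3)$beta_out, instruments(h)$beta_out)
  expect_identical(instruments(h3)$action, "kept_as_is")
})

test_that("Steiger filtering drops variants explaining more outcome variance", {
  # t_X = 10, t_Y = 2, n = 10000 on both sides -> kept
  h <- HarmonizedSet(data.frame(snp = c("keep", "drop", "tie"),
                                beta_exp = c(0.10, 0.01, 0.05),
                                se_exp = c(0.01, 0.01, 0.01),
                                beta_out = c(0.02, 0.50, 0.05),
                                se_out = c(0.01, 0.01, 0.01),
                                n_exp = 10000, n_out = 10000))
  out <- steigerFilter(h)
  diag <- mrMetadata(out)$steiger
  expect_equal(diag$r2_exp[diag$snp == "keep"], 100 / 10098, tolerance = 1e-12)
  expect_equal(diag$r2_out[diag$snp == "keep"], 4 / 10002, tolerance = 1e-12)
  expect_true("keep" %in% instruments(out)$snp)
  # t_X = 1, t_Y = 50 -> dropped
  expect_false("drop" %in% instruments(out)$snp)
  # exact tie -> retained with flag
  expect_true("tie" %in% instruments(out)$snp)
  expect_true(diag$tie[diag$snp == "tie"])
  # decisions agree with direct recomputation for every variant
  r2 <- function(b, s, n) { t2 <- (b / s)^2; t2 / (t2 + n - 2) }
  d <- instruments(h)
  manual <- r2(d$beta_out, d$se_out, d$n_out) <= r2(d$beta_exp, d$se_exp, d$n_exp)
  expect_identical(diag$kept, manual)
})

test_that("Steiger diagnostics include a Fisher-z p-value and honor n args", {
  h <- makeHS(0.1, 0.02, 0.01)
  out <- steigerFilter(h, nExp = 5000, nOut = 8000)
  diag <- mrMetadata(out)$steiger
  expect_true(is.finite(diag$steiger_pval) && diag$steiger_pval <= 1)
  expect_error(steigerFilter(h), "sample sizes")
})

test_that("each selection filter returns a subset (pipeline monotonicity)", {
  pair <- generatePair(scenarioPresets(seed = 3)$screen_demo)
  s1 <- selectByPvalue(pair$exposure)
  s2 <- suppressWarnings(ldClump(s1, pair$ld))
  s3 <- removePalindromic(s2)
  expect_true(all(variants(s1)$snp %in% variants(pair$exposure)$snp))
  expect_true(all(variants(s2)$snp %in% variants(s1)$snp))
  expect_true(all(variants(s3)$snp %in% variants(s2)$snp))
  expect_true(nVariants(s1) >= nVariants(s2))
  expect_true(nVariants(s2) >= nVariants(s3))
})
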