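test_that("the Wald ratio divides effects and guards the zero denominator", {
  expect_identical(waldRatio(makeHS(0.1, 0, 0.01))@theta, 0)
  est <- waldRatio(makeHS(0.1, 0.05, 0.01))
  expect_equal(est@theta, 0.5, tolerance = 1e-12)
  expect_equal(est@se, 0.1, tolerance = 1e-12)
  expect_error(waldRatio(makeHS(0, 0.05, 0.01)), "beta_exp is zero")
  # second-order SE incorporates exposure uncertainty and is never smaller
  est2 <- waldRatio(makeHS(0.1, 0.05, 0.01, sx = 0.02), secondOrder = TRUE)
  expect_gt(est2@se, est@se)
})

test_that("IVW reproduces hand-computed estimates and heterogeneity", {
  # identical ratios: zero heterogeneity, no overdispersion
  fit <- mrIvw(makeHS(c(1, 2), c(0.5, 1.0), c(0.1, 0.1)))
  expect_equal(fit$estimate@theta, 0.5, tolerance = 1e-12)
  expect_equal(fit$heterogeneity@Q, 0, tolerance = 1e-12)
  expect_identical(fit$estimate@scaleFactor, 1)

  # weighted least squares through the origin, hand-evaluated
  fit2 <- mrIvw(makeHS(c(0.1, 0.2, 0.3), c(0.05, 0.04, 0.12),
                       c(0.01, 0.02, 0.03)))
  expect_equal(fit2$estimate@theta, 11 / 30, tolerance = 1e-12)

  # Q with equal weights 100
  fit3 <- mrIvw(makeHS(c(1, 1), c(0.4, 0.6), c(0.1, 0.1)))
  expect_equal(fit3$estimate@theta, 0.5, tolerance = 1e-12)
  expect_equal(fit3$heterogeneity@Q, 2.0, tolerance = 1e-12)

  expect_error(mrIvw(makeHS(1, 0.5, 0.1)), "at least 2")
})

test_that("IVW equals the inverse-variance-weighted mean of Wald ratios", {
  for (seed in 1:25) {
    h <- randomHS(sample(3:30, 1), seed)
    d <- instruments(h)
    ratios <- d$beta_out / d$beta_exp
    w <- d$beta_exp^2 / d$se_out^2
    expect_equal(mrIvw(h)$estimate@theta, sum(w * ratios) / sum(w),
                 tolerance = 1e-10)
  }
})

test_that("Egger recovers a perfect line and matches the WLS oracle", {
  h <- makeHS(c(1, 2, 3), 0.1 + 0.5 * c(1, 2, 3), rep(0.1, 3))
  eg <- mrEgger(h)
  expect_equal(eg$slope@theta, 0.5, tolerance = 1e-10)
  expect_equal(eg$intercept@theta, 0.1, tolerance = 1e-10)
  expect_equal(eg$heterogeneity@Q, 0, tolerance = 1e-10)

  # random instances against the independent normal-equations oracle
  for (seed in 1:25) {
    h <- randomHS(sample(4:30, 1), seed + 100)
    d <- instruments(h)
    flip <- d$beta_exp < 0
    bx <- abs(d$beta_exp)
    by <- ifelse(flip, -d$beta_out, d$beta_out)
    o <- wlsOracle(bx, by, 1 / d$se_out^2)
    eg <- mrEgger(h)
    expect_equal(eg$slope@theta, o$slope, tolerance = 1e-8)
    expect_equal(eg$intercept@theta, o$intercept, tolerance = 1e-8)
    expect_equal(eg$slope@se, o$seSlope, tolerance = 1e-8)
    expect_equal(eg$intercept@se, o$seIntercept, tolerance = 1e-8)
  }

  expect_error(mrEgger(makeHS(c(1, 2), c(0.5, 1), c(0.1, 0.1))), "at least 3")
  expect_error(mrEgger(makeHS(c(1, 1, 1), c(0.4, 0.5, 0.6), rep(0.1, 3))),
               "collinear")
})

test_that("Egger with the intercept forced to zero reproduces IVW", {
  for (seed in 1:10) {
    h <- randomHS(sample(3:20, 1), seed + 200)
    expect_equal(mrEgger(h, forceNullIntercept = TRUE)$slope@theta,
                 mrIvw(h)$estimate@theta, tolerance = 1e-10)
  }
})

test_that("the weighted median interpolates the weighted ratio quantile", {
  # equal weights, odd count: plain median (p_2 = 1/2 exactly)
  h <- makeHS(c(1, 1, 1), c(0.2, 0.5, 0.9), rep(0.1, 3))
  expect_equal(mrWeightedMedian(h, 100, seed = 1)@theta, 0.5,
               tolerance = 1e-12)
  # equal weights, even count: interpolation between 0.2 and 0.6 -> 0.4
  h4 <- makeHS(c(1, 1, 1, 1), c(0.1, 0.2, 0.6, 0.7), rep(0.1, 4))
  expect_equal(mrWeightedMedian(h4, 100, seed = 1)@theta, 0.4,
               tolerance = 1e-12)
  # dominant-weight limit: as one variant's weight approaches 1 the
  # estimate converges to its ratio
  hd <- makeHS(c(3000, 1, 1), c(3000 * 0.3, 2.0, 2.0), c(0.1, 0.1, 0.1))
  expect_lt(abs(mrWeightedMedian(hd, 100, seed = 1)@theta - 0.3), 1e-6)
  expect_error(mrWeightedMedian(makeHS(c(1, 1), c(1, 1), c(0.1, 0.1)),
                                100, seed = 1), "at least 3")
  expect_error(mrWeightedMedian(h, 50, seed = 1), "nBoot")
  expect_error(mrWeightedMedian(h, 100), "seed")
})

test_that("the weighted median stays within the ratio range and ignores order", {
  for (seed in 1:20) {
    h <- randomHS(sample(3:25, 1), seed + 300)
    d <- instruments(h)
    est <- mrWeightedMedian(h, 100, seed = 5)@theta
    ratios <- d$beta_out / d$beta_exp
    expect_gte(est, min(ratios))
    expect_lte(est, max(ratios))
    perm <- d[sample.int(nrow(d)), , drop = FALSE]
    expect_equal(mrWeightedMedian(HarmonizedSet(perm), 100, seed = 5)@theta,
                 est, tolerance = 1e-12)
  }
})

test_that("negating outcome effects negates every estimator (sign equivariance)", {
  h <- randomHS(12, 7)
  d <- instruments(h)
  neg <- d; neg$beta_out <- -neg$beta_out
  hn <- HarmonizedSet(neg)
  expect_equal(mrIvw(hn)$estimate@theta, -mrIvw(h)$estimate@theta,
               tolerance = 1e-12)
  expect_equal(mrEgger(hn)$slope@theta, -mrEgger(h)$slope@theta,
               tolerance = 1e-12)
  expect_equal(mrWeightedMedian(hn, 100, seed = 2)@theta,
               -mrWeightedMedian(h, 100, seed = 2)@theta, tolerance = 1e-12)
  one <- HarmonizedSet(d[1, ]); oneN <- HarmonizedSet(neg[1, ])
  expect_equal(waldRatio(oneN)@theta, -waldRatio(one)@theta,
               tolerance = 1e-12)
  # and maps the odds ratio to its reciprocal
  orP <- toOddsRatio(mrIvw(h)$estimate)
  orN <- toOddsRatio(mrIvw(hn)$estimate)
  expect_equal(orN@or, 1 / orP@or, tolerance = 1e-12)
})

test_that("odds-ratio conversion exponentiates and preserves ordering", {
  null <- .newEstimateForTest(0, 0.1)
  expect_equal(toOddsRatio(null)@or, 1, tolerance = 1e-12)
  est <- .newEstimateForTest(log(2), 0.1 / 1.959964)
  orr <- toOddsRatio(est)
  expect_equal(orr@or, 2, tolerance = 1e-12)
  expect_equal(orr@orLow, exp(log(2) - 0.1), tolerance = 1e-9)
  expect_equal(orr@orHigh, exp(log(2) + 0.1), tolerance = 1e-9)
  for (seed in 1:10) {
    h <- randomHS(8, seed + 400)
    o <- toOddsRatio(mrIvw(h)$estimate)
    expect_true(o@orLow <= o@or && o@or <= o@orHigh)
  }
})
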