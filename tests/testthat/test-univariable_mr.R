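test_that("Wald ratio follows the delta-method formulae", {
  wr <- waldRatio(1.0, 0.01, 0.2, 0.1)
  expect_equal(wr$ratio, 0.2)
  expect_equal(wr$se, 0.1)

  wr2 <- waldRatio(0.2, 0.01, 0.04, 0.02)
  expect_equal(wr2$ratio, 0.2)
  expect_equal(wr2$se, 0.1)

  # second-order term from the symbolic delta expansion of by/bx
  wr3 <- waldRatio(0.2, 0.05, 0.04, 0.02, secondOrder = TRUE)
  expect_equal(wr3$se, sqrt(0.02^2 / 0.2^2 + 0.04^2 * 0.05^2 / 0.2^4))

  expect_error(waldRatio(0, 0.01, 0.1, 0.02, variantId = "rs1"), "rs1")
})

test_that("IVW matches the closed form and its weighted-regression oracle", {
  h <- makeHarmonized(bx = c(0.1, 0.2, 0.4), sx = rep(0.01, 3),
                      by = c(0.02, 0.05, 0.09), sy = c(0.01, 0.01, 0.02))
  r <- mrIvw(h, model = "fixed")
  w <- 1 / c(0.01, 0.01, 0.02)^2
  closed <- sum(w * c(0.1, 0.2, 0.4) * c(0.02, 0.05, 0.09)) /
    sum(w * c(0.1, 0.2, 0.4)^2)
  expect_equal(mrBeta(r), closed, tolerance = 1e-14)

  fit <- lm(c(0.02, 0.05, 0.09) ~ 0 + c(0.1, 0.2, 0.4), weights = w)
  expect_equal(mrBeta(r), unname(coef(fit)), tolerance = 1e-12)

  # fixed-effect se is the design-based one (residual dispersion fixed at 1)
  expect_equal(mrSE(r), sqrt(1 / sum(w * c(0.1, 0.2, 0.4)^2)),
               tolerance = 1e-14)
})

test_that("IVW reduces to the Wald ratio with one variant and the equal-weight mean with symmetric designs", {
  h1 <- makeHarmonized(bx = 0.25, sx = 0.01, by = 0.05, sy = 0.02)
  r1 <- mrIvw(h1)
  expect_equal(mrBeta(r1), 0.05 / 0.25)
  expect_equal(mrSE(r1), 0.02 / 0.25)

  # two ratios 0.1 and 0.3 with equal outcome se and equal exposure betas
  h2 <- makeHarmonized(bx = c(0.2, 0.2), sx = rep(0.01, 2),
                       by = c(0.02, 0.06), sy = rep(0.01, 2))
  expect_equal(mrBeta(mrIvw(h2)), 0.2, tolerance = 1e-14)
})

test_that("random-effects IVW never deflates the fixed-effect se", {
  for (seed in 1:10) {
    h <- randomHarmonized(15, seed)
    expect_gte(mrSE(mrIvw(h, "multiplicative_random")),
               mrSE(mrIvw(h, "fixed")) - 1e-15)
  }
})

test_that("Egger recovers an exact linear law and matches the WLS oracle", {
  bx <- c(0.1, 0.15, 0.2, 0.3, 0.4)
  by <- 0.05 + 0.4 * bx
  h <- makeHarmonized(bx = bx, sx = rep(0.01, 5), by = by,
                      sy = rep(0.02, 5))
  r <- mrEgger(h)
  expect_equal(mrBeta(r), 0.4, tolerance = 1e-10)
  expect_equal(unname(eggerIntercept(r)["estimate"]), 0.05,
               tolerance = 1e-10)

  # independent oracle: weighted lm on sign-oriented data
  for (seed in 1:10) {
    hh <- randomHarmonized(12, seed + 100)
    d <- harmonizedData(hh)
    s <- ifelse(d$beta_exposure < 0, -1, 1)
    fit <- lm(I(s * d$beta_outcome) ~ I(s * d$beta_exposure),
              weights = 1 / d$se_outcome^2)
    rr <- mrEgger(hh)
    expect_equal(mrBeta(rr), unname(coef(fit)[2]), tolerance = 1e-10)
    expect_equal(unname(eggerIntercept(rr)["estimate"]),
                 unname(coef(fit)[1]), tolerance = 1e-10)
  }

  expect_error(mrEgger(makeHarmonized(bx = c(0.1, 0.2), sx = rep(0.01, 2),
                                      by = c(0.02, 0.05),
                                      sy = rep(0.01, 2))),
               ">= 3")
})

test_that("weighted median matches the quantile definition and the ordinary median under equal weights", {
  h <- makeHarmonized(bx = rep(1, 3), sx = rep(0.01, 3),
                      by = c(0.1, 0.2, 0.9), sy = rep(0.05, 3))
  r <- mrWeightedMedian(h, nBoot = 50, seed = 1)
  expect_equal(mrBeta(r), 0.2)

  # brute-force weighted-quantile oracle for ratios {0.1, 0.2}, weights {1, 3}
  # cumulative midpoints p = (0.125, 0.625); interpolate to 0.5:
  oracle <- approx(c(0.125, 0.625), c(0.1, 0.2), xout = 0.5)$y
  est <- mrmediate:::.weightedMedian(c(0.1, 0.2), c(1, 3))
  expect_equal(est, oracle)

  # equal weights equal the ordinary median, odd and even k
  for (k in c(5, 6)) {
    set.seed(k)
    x <- rnorm(k)
    expect_equal(mrmediate:::.weightedMedian(x, rep(2, k)), median(x))
  }
})

test_that("weighted median resists up to half the weight being invalid", {
  # 49% of the weight shifted by +1: with precise valid ratios the
  # estimate stays at the valid cluster, far from the contaminated mean
  set.seed(60)
  k <- 201
  bx <- rep(1, k)
  truth <- 0.2
  sy <- rep(0.002, k)
  by <- rnorm(k, truth, sy)
  shift <- seq_len(k) <= floor(0.49 * k)
  by[shift] <- by[shift] + 1
  h <- makeHarmonized(bx = bx, sx = rep(1e-4, k), by = by, sy = sy)
  r <- mrWeightedMedian(h, nBoot = 200, seed = 2)
  expect_lt(abs(mrBeta(r) - truth), 0.02)
  expect_gt(abs(mean(by) - truth), 0.4)
})

test_that("contamination mixture handles degenerate and single-variant sets", {
  h <- makeHarmonized(bx = rep(1, 5), sx = rep(0.001, 5),
                      by = rep(0.2, 5), sy = rep(0.001, 5))
  r <- mrConMix(h, psi = 0.5)
  expect_equal(mrBeta(r), 0.2, tolerance = 1e-10)
  ci <- mrCI(r)
  expect_lte(ci["low"], mrBeta(r))
  expect_gte(ci["high"], mrBeta(r))

  h1 <- makeHarmonized(bx = 0.5, sx = 0.01, by = 0.15, sy = 0.05)
  expect_equal(mrBeta(mrConMix(h1, psi = 1)), 0.3, tolerance = 1e-10)
})

test_that("contamination mixture recovers the valid component under contamination", {
  set.seed(61)
  k <- 100
  valid <- seq_len(k) <= 70
  bx <- rep(1, k)
  by <- ifelse(valid, rnorm(k, 0.2, 0.02), rnorm(k, 0.8, 0.1))
  h <- makeHarmonized(bx = bx, sx = rep(0.001, k), by = by,
                      sy = rep(0.02, k))
  r <- mrConMix(h)
  expect_lt(abs(mrBeta(r) - 0.2), 0.02)
})

test_that("MR-PRESSO validates inputs and flags a planted outlier", {
  h <- randomHarmonized(10, 70)
  expect_error(mrPresso(h, nSimulations = 0), "nSimulations")
  expect_error(mrPresso(makeHarmonized(bx = c(1, 1, 1), sx = rep(0.01, 3),
                                       by = c(0.1, 0.2, 0.3),
                                       sy = rep(0.01, 3))),
               ">= 4")

  set.seed(71)
  k <- 50
  bx <- rnorm(k, 0.2, 0.05)
  sy <- rep(0.02, k)
  by <- rnorm(k, 0.3 * bx, sy)
  by[7] <- 0.3 * bx[7] + 10 * sy[7]
  h2 <- makeHarmonized(bx = bx, sx = rep(0.001, k), by = by, sy = sy)
  pr <- mrPresso(h2, nSimulations = 1000, seed = 3)
  expect_true("s0007" %in% pressoOutliers(pr))
  expect_lt(pressoGlobalP(pr), 0.05)
  expect_equal(nVariants(pressoCorrected(pr)),
               nVariants(pressoRaw(pr)) - length(pressoOutliers(pr)))
  # corrected estimate moves back toward the generating slope
  expect_lt(abs(mrBeta(pressoCorrected(pr)) - 0.3),
            abs(mrBeta(pressoRaw(pr)) - 0.3))

  # no outliers flagged => corrected equals raw
  by3 <- rnorm(k, 0.3 * bx, sy)
  h3 <- makeHarmonized(bx = bx, sx = rep(0.001, k), by = by3, sy = sy)
  pr3 <- mrPresso(h3, nSimulations = 500, seed = 4)
  if (length(pressoOutliers(pr3)) == 0)
    expect_equal(mrBeta(pressoCorrected(pr3)), mrBeta(pressoRaw(pr3)))
})

test_that("MR-PRESSO is deterministic given its seed", {
  h <- randomHarmonized(20, 72)
  a <- mrPresso(h, nSimulations = 200, seed = 9)
  b <- mrPresso(h, nSimulations = 200, seed = 9)
  expect_identical(pressoGlobalP(a), pressoGlobalP(b))
  expect_identical(pressoOutliers(a), pressoOutliers(b))
})

test_that("estimate transformation rescales and exponentiates correctly", {
  r <- makeHarmonized(bx = 1, sx = 0.01, by = 0.017, sy = 0.005)
  est <- mrIvw(r)
  per10 <- transformEstimate(est, 10)
  expect_equal(mrBeta(per10), 0.17, tolerance = 1e-12)
  expect_equal(mrSE(per10), 0.05, tolerance = 1e-12)

  zero <- makeHarmonized(bx = 1, sx = 0.01, by = 0, sy = 0.005)
  or1 <- transformEstimate(mrIvw(zero), 1, asOddsRatio = TRUE)
  expect_equal(mrBeta(or1), 1.0)

  tpl <- new("MrResult", method = "ivw", beta = 0.1, se = 0.051,
             ciLow = 0.0, ciHigh = 0.2, pvalue = 0.05, nVariants = 5L)
  or <- transformEstimate(tpl, 1, asOddsRatio = TRUE)
  expect_equal(mrBeta(or), exp(0.1), tolerance = 1e-12)
  expect_equal(unname(mrCI(or)), c(exp(0), exp(0.2)), tolerance = 1e-12)

  expect_error(transformEstimate(tpl, 0), "nonzero")
})

test_that("estimators are equivariant under exposure-unit rescaling", {
  h <- randomHarmonized(20, 73)
  c_ <- 2.5
  d <- harmonizedData(h)
  hs <- makeHarmonized(bx = d$beta_exposure * c_,
                       sx = d$se_exposure * c_,
                       by = d$beta_outcome, sy = d$se_outcome)
  expect_equal(mrBeta(mrIvw(hs)), mrBeta(mrIvw(h)) / c_, tolerance = 1e-12)
  expect_equal(mrBeta(mrEgger(hs)), mrBeta(mrEgger(h)) / c_,
               tolerance = 1e-12)
  expect_equal(mrBeta(mrWeightedMedian(hs, nBoot = 10, seed = 1)),
               mrBeta(mrWeightedMedian(h, nBoot = 10, seed = 1)) / c_,
               tolerance = 1e-12)
})
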