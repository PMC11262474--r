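test_that("MVMR with a zero mediator column reduces to univariable fixed-effect IVW", {
  h <- randomHarmonized(12, 80)
  d <- harmonizedData(h)
  h0 <- makeHarmonized(bx = d$beta_exposure, sx = d$se_exposure,
                       by = d$beta_outcome, sy = d$se_outcome,
                       bm = rep(0, 12), sm = rep(0.01, 12))
  fit <- mvmrIvw(h0)
  uni <- mrIvw(h, model = "fixed")
  expect_identical(unname(mrBeta(fit)[1]), mrBeta(uni))
  expect_true(is.na(mrBeta(fit)[2]))
})

test_that("noiseless joint data are recovered exactly", {
  set.seed(81)
  k <- 15
  bx <- rnorm(k, 0, 0.1)
  bm <- 0.4 * bx + rnorm(k, 0, 0.1)  # mediator has independent variation
  by <- 0.3 * bx + 0.5 * bm
  h <- makeHarmonized(bx = bx, sx = rep(1e-6, k), by = by,
                      sy = rep(0.01, k), bm = bm, sm = rep(1e-6, k))
  fit <- mvmrIvw(h)
  expect_equal(unname(mrBeta(fit)), c(0.3, 0.5), tolerance = 1e-10)

  q <- qhetMvmr(h, nBoot = 0)
  expect_equal(unname(mrBeta(q)), c(0.3, 0.5), tolerance = 1e-6)
})

test_that("MVMR-IVW equals the generalized-least-squares oracle", {
  for (seed in 1:10) {
    h <- randomHarmonized(20, seed + 200, mediator = TRUE)
    d <- harmonizedData(h)
    fit <- mvmrIvw(h)
    lmfit <- lm(d$beta_outcome ~ 0 + d$beta_exposure + d$beta_mediator,
                weights = 1 / d$se_outcome^2)
    expect_equal(unname(mrBeta(fit)), unname(coef(lmfit)),
                 tolerance = 1e-10)
  }
})

test_that("collinear exposure and mediator columns raise an estimation error", {
  set.seed(82)
  bx <- rnorm(10, 0, 0.1)
  h <- makeHarmonized(bx = bx, sx = rep(0.01, 10),
                      by = rnorm(10, 0, 0.05), sy = rep(0.02, 10),
                      bm = 2 * bx, sm = rep(0.01, 10))
  expect_error(mvmrIvw(h), "rank-deficient")
})

test_that("conditional F has the documented limits", {
  set.seed(83)
  k <- 20
  bx <- rnorm(k, 0, 0.1)
  sx <- rep(0.01, k)
  # nothing to condition on: mediator identically zero
  h0 <- makeHarmonized(bx = bx, sx = sx, by = rnorm(k, 0, 0.05),
                       sy = rep(0.02, k), bm = rep(0, k),
                       sm = rep(0.01, k))
  cf0 <- conditionalF(h0)
  expect_equal(unname(cf0[1]), mean((bx / sx)^2), tolerance = 1e-12)

  # perfectly collinear: no independent variation left
  h1 <- makeHarmonized(bx = bx, sx = sx, by = rnorm(k, 0, 0.05),
                       sy = rep(0.02, k), bm = 3 * bx, sm = rep(0.01, k))
  cf1 <- conditionalF(h1)
  expect_lt(unname(cf1[1]), 1e-18)
  expect_lt(unname(cf1[2]), 1e-16)
})

test_that("Qhet matches MVMR-IVW in the no-measurement-error limit", {
  set.seed(84)
  k <- 25
  bx <- rnorm(k, 0, 0.1)
  bm <- 0.3 * bx + rnorm(k, 0, 0.08)
  by <- rnorm(k, 0.25 * bx + 0.6 * bm, 0.02)
  h <- makeHarmonized(bx = bx, sx = rep(1e-8, k), by = by,
                      sy = rep(0.02, k), bm = bm, sm = rep(1e-8, k))
  ivw <- mvmrIvw(h)
  q <- qhetMvmr(h, nBoot = 0)
  expect_equal(unname(mrBeta(q)), unname(mrBeta(ivw)), tolerance = 1e-6)
})

test_that("Qhet attains zero heterogeneity on exact-linear data", {
  set.seed(85)
  k <- 12
  bx <- rnorm(k, 0, 0.1)
  bm <- 0.5 * bx + rnorm(k, 0, 0.1)
  by <- 0.2 * bx + 0.7 * bm
  h <- makeHarmonized(bx = bx, sx = rep(0.01, k), by = by,
                      sy = rep(0.02, k), bm = bm, sm = rep(0.01, k))
  q <- qhetMvmr(h, nBoot = 0)
  est <- mrBeta(q)
  qval <- sum((by - est[1] * bx - est[2] * bm)^2 /
                (0.02^2 + est[1]^2 * 0.01^2 + est[2]^2 * 0.01^2))
  expect_lt(qval, 1e-8)
  expect_equal(unname(est), c(0.2, 0.7), tolerance = 1e-4)
})

test_that("mediation decomposition follows the stated arithmetic", {
  mk_total <- function(b, se) new("MrResult", method = "ivw", beta = b,
                                  se = se, ciLow = b - 1.96 * se,
                                  ciHigh = b + 1.96 * se, pvalue = 0.01,
                                  nVariants = 10L)
  mk_mvmr <- function(direct, my) new("MvmrResult", method = "mvmr_ivw",
                                      exposures = c("X", "M"),
                                      beta = c(X = direct, M = my),
                                      se = c(X = 0.01, M = 0.02),
                                      ciLow = c(X = direct - 0.02,
                                                M = my - 0.04),
                                      ciHigh = c(X = direct + 0.02,
                                                 M = my + 0.04),
                                      pvalue = c(X = 0.01, M = 0.01),
                                      conditionalF = c(X = NA_real_,
                                                       M = NA_real_),
                                      nVariants = 10L)
  xm <- mk_total(0.2, 0.01)

  d1 <- decomposeMediation(mk_total(-0.05, 0.01), mk_mvmr(-0.05, 0.5), xm,
                           ciMethod = "delta")
  expect_equal(indirectEffect(d1)[1], 0)
  expect_equal(proportionMediated(d1)[1], 0)

  d2 <- decomposeMediation(mk_total(-0.04, 0.01), mk_mvmr(-0.05, 0.5), xm,
                           ciMethod = "delta")
  expect_equal(indirectEffect(d2)[1], 0.01)
  expect_equal(proportionMediated(d2)[1], -0.25)

  d3 <- decomposeMediation(mk_total(0.4, 0.01), mk_mvmr(0.3, 0.5), xm,
                           ciMethod = "delta")
  expect_equal(indirectEffect(d3, "product")[1], 0.2 * 0.5)
  expect_equal(proportionMediated(d3, "product")[1], 0.25)

  expect_error(decomposeMediation(mk_total(0, 0.01), mk_mvmr(0.3, 0.5), xm),
               "undefined-proportion")

  # bootstrap CIs are deterministic given the seed
  b1 <- decomposeMediation(mk_total(0.4, 0.05), mk_mvmr(0.3, 0.5), xm,
                           ciMethod = "bootstrap", nBoot = 500, seed = 7)
  b2 <- decomposeMediation(mk_total(0.4, 0.05), mk_mvmr(0.3, 0.5), xm,
                           ciMethod = "bootstrap", nBoot = 500, seed = 7)
  expect_identical(proportionMediated(b1), proportionMediated(b2))
})
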