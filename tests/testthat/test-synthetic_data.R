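test_that("noiseless limit reproduces the structural betas exactly", {
  cfg <- simulationConfig(nVariants = 50, causalFraction = 1,
                          mediatorSpecificFraction = 0, deltaSd = 0,
                          thetaDirect = 0.5, thetaXM = 0, thetaMY = 0,
                          pleiotropyMode = "none", noiseless = TRUE,
                          seed = 2)
  sim <- simulateTriplet(cfg)
  expect_identical(gwasData(sim$outcome)$beta, 0.5 * trueGamma(sim$truth))
  expect_identical(gwasData(sim$exposure)$beta, trueGamma(sim$truth))
})

test_that("structural truth identities hold by construction", {
  cfg <- simulationConfig(thetaXM = 0.2, thetaMY = 1.0, thetaDirect = 0,
                          seed = 4)
  truth <- simulateTriplet(cfg)$truth
  expect_identical(trueProportionMediated(truth), 1.0)
  th <- trueTheta(truth)
  expect_identical(th[["total"]],
                   th[["direct"]] + th[["xm"]] * th[["my"]])
})

test_that("simulation is deterministic given the seed", {
  cfg <- simulationConfig(nVariants = 1000, thetaXM = 0.3, thetaMY = 0.2,
                          thetaDirect = 0.1, pleiotropyMode = "balanced",
                          alphaSd = 0.01, seed = 99)
  a <- simulateTriplet(cfg)
  b <- simulateTriplet(cfg)
  expect_identical(gwasData(a$exposure), gwasData(b$exposure))
  expect_identical(gwasData(a$outcome), gwasData(b$outcome))
  expect_identical(ldR(a$ld), ldR(b$ld))
})

test_that("standard errors scale exactly as 1/sqrt(N)", {
  cfg1 <- simulationConfig(nVariants = 40, nExposure = 100000, seed = 6)
  cfg2 <- simulationConfig(nVariants = 40, nExposure = 200000, seed = 6)
  se1 <- gwasData(simulateTriplet(cfg1)$exposure)$se
  se2 <- gwasData(simulateTriplet(cfg2)$exposure)$se
  expect_equal(se2, se1 / sqrt(2), tolerance = 1e-15)
})

test_that("proportion mediated is invariant to rescaling the variant effects", {
  base <- list(thetaXM = 0.4, thetaMY = 0.5, thetaDirect = 0.3)
  t1 <- simulateTriplet(do.call(simulationConfig,
                                c(base, gammaSd = 0.02, seed = 8)))$truth
  t2 <- simulateTriplet(do.call(simulationConfig,
                                c(base, gammaSd = 0.1, seed = 8)))$truth
  expect_identical(trueProportionMediated(t1), trueProportionMediated(t2))
})

test_that("winner's curse: no selection at threshold 1; inflation for null variants; negligible far from the boundary", {
  cfg <- simulationConfig(nVariants = 100, seed = 10)
  sim <- simulateTriplet(cfg)
  same <- applyWinnersCurse(sim$exposure, sim$truth, 1)
  expect_identical(gwasData(same), gwasData(sim$exposure))
  expect_error(applyWinnersCurse(sim$exposure, sim$truth, 0), "validation")

  # null variants: every discovered estimate must clear the significance
  # boundary, so |beta| is inflated relative to the (zero) truth
  n <- 20000
  z <- qnorm(1 - 5e-8 / 2)
  null_tab <- GwasTable(data.frame(
    variant_id = sprintf("n%05d", seq_len(n)), effect_allele = "A",
    other_allele = "G", eaf = 0.5, beta = rnorm(n, 0, 0.01), se = 0.01,
    n = 1e5), checkPvalues = FALSE)
  null_truth <- new("SimulationTruth", gamma = rep(0, n), delta = rep(0, n),
                    alpha = rep(0, n), thetaXM = 0, thetaMY = 0,
                    thetaDirect = 0, thetaTotal = 0,
                    proportionMediatedTrue = NA_real_)
  cursed <- applyWinnersCurse(null_tab, null_truth, 5e-8, seed = 1)
  expect_gt(nrow(gwasData(cursed)), 0)
  tt <- t.test(abs(gwasData(cursed)$beta), mu = 0, alternative = "greater")
  expect_lt(tt$p.value, 0.001)
  expect_true(all(abs(gwasData(cursed)$beta) > z * 0.01))

  # far from the boundary (|beta|/se > 10) truncation is negligible:
  # Monte-Carlo mean of the conditional draw within 1% of the true beta
  m <- 20000
  mu <- 0.12; s <- 0.01  # z = 12
  far_tab <- GwasTable(data.frame(
    variant_id = sprintf("f%05d", seq_len(m)), effect_allele = "A",
    other_allele = "G", eaf = 0.5, beta = rnorm(m, mu, s), se = s, n = 1e5),
    checkPvalues = FALSE)
  far_truth <- new("SimulationTruth", gamma = rep(mu, m),
                   delta = rep(0, m), alpha = rep(0, m), thetaXM = 0,
                   thetaMY = 0, thetaDirect = 0, thetaTotal = 0,
                   proportionMediatedTrue = NA_real_)
  far <- applyWinnersCurse(far_tab, far_truth, 5e-8, seed = 2)
  expect_lt(abs(mean(gwasData(far)$beta) - mu) / mu, 0.01)
})

test_that("covariable adjustment is the identity at zero strength or zero effects", {
  cfg <- simulationConfig(nVariants = 60, seed = 12)
  tab <- simulateTriplet(cfg)$exposure
  expect_identical(gwasData(applyCovariableAdjustment(tab, 0, rnorm(60)))$beta,
                   gwasData(tab)$beta)
  expect_identical(gwasData(applyCovariableAdjustment(tab, 0.5,
                                                      rep(0, 60)))$beta,
                   gwasData(tab)$beta)
  expect_error(applyCovariableAdjustment(tab, 0.5, rnorm(10)),
               "validation")
})

test_that("covariable adjustment shifts the per-variant betas by -strength * effect", {
  cfg <- simulationConfig(nVariants = 30, seed = 13)
  tab <- simulateTriplet(cfg)$exposure
  eff <- rnorm(30, 0, 0.02)
  adj <- applyCovariableAdjustment(tab, 0.4, eff)
  expect_equal(gwasData(adj)$beta, gwasData(tab)$beta - 0.4 * eff,
               tolerance = 1e-15)
})
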