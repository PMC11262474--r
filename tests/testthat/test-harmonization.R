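makePair <- function(ea_o, oa_o, beta_o = 0.03) {
  ex <- GwasTable(data.frame(variant_id = "v1", effect_allele = "A",
                             other_allele = "G", eaf = 0.3, beta = 0.1,
                             se = 0.01, n = 1e4), checkPvalues = FALSE)
  ou <- GwasTable(data.frame(variant_id = "v1", effect_allele = ea_o,
                             other_allele = oa_o, eaf = 0.7, beta = beta_o,
                             se = 0.02, n = 1e4), checkPvalues = FALSE)
  list(ex = ex, ou = ou)
}

test_that("swapped outcome alleles flip the outcome effect sign", {
  p <- makePair("G", "A", beta_o = 0.03)
  h <- harmonize(p$ex, p$ou)
  expect_equal(harmonizedData(h)$beta_outcome, -0.03)
  expect_equal(h@nFlipped, 1L)
  expect_equal(nDroppedMismatch(h), 0L)
})

test_that("palindromic variants are retained unchanged on nominal labels", {
  ex <- GwasTable(data.frame(variant_id = "v1", effect_allele = "A",
                             other_allele = "T", beta = 0.1, se = 0.01,
                             n = 1e4), checkPvalues = FALSE)
  ou <- GwasTable(data.frame(variant_id = "v1", effect_allele = "A",
                             other_allele = "T", beta = 0.05, se = 0.02,
                             n = 1e4), checkPvalues = FALSE)
  h <- harmonize(ex, ou)
  expect_equal(nVariants(h), 1L)
  expect_equal(harmonizedData(h)$beta_outcome, 0.05)
  expect_equal(h@nFlipped, 0L)
})

test_that("irreconcilable allele pairs are dropped and counted", {
  p <- makePair("A", "C")
  h <- harmonize(p$ex, p$ou)
  expect_equal(nVariants(h), 0L)
  expect_equal(nDroppedMismatch(h), 1L)
})

test_that("harmonization is idempotent", {
  cfg <- simulationConfig(nVariants = 40, thetaDirect = 0.3, seed = 50)
  sim <- simulateTriplet(cfg)
  h1 <- harmonize(sim$exposure, sim$outcome)
  # re-harmonize the harmonized views of each side
  hv <- harmonizedData(h1)
  exp2 <- GwasTable(data.frame(variant_id = hv$variant_id,
                               effect_allele = hv$effect_allele,
                               other_allele = hv$other_allele,
                               beta = hv$beta_exposure,
                               se = hv$se_exposure, n = 1e4),
                    checkPvalues = FALSE)
  out2 <- GwasTable(data.frame(variant_id = hv$variant_id,
                               effect_allele = hv$effect_allele,
                               other_allele = hv$other_allele,
                               beta = hv$beta_outcome,
                               se = hv$se_outcome, n = 1e4),
                    checkPvalues = FALSE)
  h2 <- harmonize(exp2, out2)
  expect_equal(harmonizedData(h2)$beta_outcome, hv$beta_outcome)
  expect_equal(harmonizedData(h2)$beta_exposure, hv$beta_exposure)
})

test_that("strand-complementing non-palindromic outcome records leaves estimates unchanged", {
  cfg <- simulationConfig(nVariants = 60, causalFraction = 1,
                          gammaSd = 0.05, thetaDirect = 0.4, seed = 51)
  sim <- simulateTriplet(cfg)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ov <- gwasData(sim$outcome)
  pal <- comp[ov$effect_allele] == ov$other_allele
  ov$effect_allele[!pal] <- unname(comp[ov$effect_allele[!pal]])
  ov$other_allele[!pal] <- unname(comp[ov$other_allele[!pal]])
  flipped <- GwasTable(ov, traitLabel = "outcome", checkPvalues = FALSE)
  h1 <- mrIvw(harmonize(sim$exposure, sim$outcome))
  h2 <- mrIvw(harmonize(sim$exposure, flipped))
  expect_equal(mrBeta(h2), mrBeta(h1), tolerance = 1e-14)
  expect_equal(mrSE(h2), mrSE(h1), tolerance = 1e-14)
})

test_that("Wald ratios are invariant to globally negating both sides", {
  wr1 <- waldRatio(0.2, 0.01, 0.04, 0.02)
  wr2 <- waldRatio(-0.2, 0.01, -0.04, 0.02)
  expect_identical(wr1$ratio, wr2$ratio)
  expect_identical(wr1$se, wr2$se)
})

test_that("three-way harmonization applies intersection and alignment semantics", {
  cfg <- simulationConfig(nVariants = 30, causalFraction = 1,
                          mediatorSpecificFraction = 1, thetaXM = 0.4,
                          thetaMY = 0.5, thetaDirect = 0.2, seed = 52)
  sim <- simulateTriplet(cfg)

  # aligned tables pass through unchanged
  ids <- variantIds(sim$exposure)
  h3 <- harmonizeMulti(sim$exposure, sim$mediator, sim$outcome, ids)
  expect_equal(harmonizedData(h3)$beta_mediator, gwasData(sim$mediator)$beta)
  expect_equal(harmonizedData(h3)$beta_outcome, gwasData(sim$outcome)$beta)

  # variant absent from the mediator table is dropped
  med_v <- gwasData(sim$mediator)[-1, ]
  med2 <- GwasTable(med_v, traitLabel = "mediator", checkPvalues = FALSE)
  h3b <- harmonizeMulti(sim$exposure, med2, sim$outcome, ids)
  expect_false(ids[1] %in% variantIds(h3b))

  # an identically-zero mediator column survives as a degenerate design
  med_v0 <- gwasData(sim$mediator)
  med_v0$beta <- 0
  med0 <- GwasTable(med_v0, traitLabel = "mediator", checkPvalues = FALSE)
  h3c <- harmonizeMulti(sim$exposure, med0, sim$outcome, ids)
  expect_true(all(harmonizedData(h3c)$beta_mediator == 0))
})
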