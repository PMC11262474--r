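#' Configuration for the summary-statistics simulator
#'
#' Defines a linear structural model over `nVariants` independent-effect
#' variants: variant j has a true exposure effect `gamma_j` (nonzero with
#' probability `causalFraction`, drawn N(0, gammaSd^2)) and a
#' mediator-specific effect `delta_j` (nonzero with probability
#' `mediatorSpecificFraction`, drawn N(0, deltaSd^2)); the mediator-specific
#' effects give the mediator instruments of their own, without which the
#' two-exposure design would be unidentified. True per-variant effects are
#'
#' \deqn{b_{M,j} = \theta_{XM}\gamma_j + \delta_j}
#' \deqn{b_{Y,j} = \theta_{direct}\gamma_j + \theta_{MY} b_{M,j} + \alpha_j}
#'
#' with `alpha_j` horizontal pleiotropy (`none`: 0; `balanced`:
#' N(0, alphaSd^2); `directional`: N(alphaMean, alphaSd^2)). Observed betas
#' add N(0, se_j^2) noise with `se_j = 1/sqrt(2 f_j (1 - f_j) N_trait)`
#' (standardized-trait GWAS standard error), so doubling a sample size
#' shrinks every se by exactly 1/sqrt(2).
#'
#' Default sample sizes mirror the largest published blood-pressure
#' (N = 757,601) and intraocular-pressure (N = 139,555) GWAS meta-analyses
#' and an OCT outcome GWAS (N = 33,129), giving realistic standard-error
#' magnitudes; `gammaSd = 0.02` puts typical instruments at genome-wide
#' significance under the exposure sample size.
#'
#' @param nVariants number of variants.
#' @param causalFraction fraction of variants with nonzero exposure effect.
#' @param mediatorSpecificFraction fraction with nonzero mediator-specific
#'   effect.
#' @param eafRange interval within (0,1) for effect-allele frequencies.
#' @param gammaSd,deltaSd SDs of the true effect distributions.
#' @param nExposure,nMediator,nOutcome GWAS sample sizes.
#' @param thetaXM,thetaMY,thetaDirect structural coefficients.
#' @param pleiotropyMode `"none"`, `"balanced"` or `"directional"`.
#' @param alphaMean,alphaSd pleiotropy distribution parameters.
#' @param ldBlockSizes integer block sizes summing to `nVariants`
#'   (`NULL` = all singleton blocks, i.e. no LD).
#' @param ldWithinBlockR common correlation within each block
#'   (compound-symmetric blocks).
#' @param outcomeType `"continuous"` or `"binary"`; binary outcomes are
#'   generated on the log-odds scale with the same additive machinery.
#' @param noiseless if `TRUE`, sampling noise is suppressed (the N -> Inf
#'   limit): observed betas equal true betas while the nominal `se` columns
#'   are kept for weighting.
#' @param seed RNG seed; simulation is deterministic given the seed.
#' @return a `SimulationConfig` object.
#' @export
simulationConfig <- function(nVariants = 300L, causalFraction = 0.5,
                             mediatorSpecificFraction = 0.5,
                             eafRange = c(0.1, 0.9),
                             gammaSd = 0.02, deltaSd = 0.02,
                             nExposure = 757601, nMediator = 139555,
                             nOutcome = 33129,
                             thetaXM = 0, thetaMY = 0, thetaDirect = 0,
                             pleiotropyMode = c("none", "balanced",
                                                "directional"),
                             alphaMean = 0, alphaSd = 0,
                             ldBlockSizes = NULL, ldWithinBlockR = 0,
                             outcomeType = c("continuous", "binary"),
                             noiseless = FALSE, seed = 1L) {
  pleiotropyMode <- match.arg(pleiotropyMode)
  outcomeType <- match.arg(outcomeType)
  cfg <- list(nVariants = as.integer(nVariants),
              causalFraction = causalFraction,
              mediatorSpecificFraction = mediatorSpecificFraction,
              eafRange = eafRange, gammaSd = gammaSd, deltaSd = deltaSd,
              nExposure = nExposure, nMediator = nMediator,
              nOutcome = nOutcome, thetaXM = thetaXM, thetaMY = thetaMY,
              thetaDirect = thetaDirect, pleiotropyMode = pleiotropyMode,
              alphaMean = alphaMean, alphaSd = alphaSd,
              ldBlockSizes = ldBlockSizes, ldWithinBlockR = ldWithinBlockR,
              outcomeType = outcomeType, noiseless = isTRUE(noiseless),
              seed = as.integer(seed))
  class(cfg) <- "SimulationConfig"
  .validateSimulationConfig(cfg)
  cfg
}

.validateSimulationConfig <- function(cfg) {
  if (cfg$nVariants < 1L)
    stop("validation error: nVariants must be >= 1")
  if (cfg$causalFraction <= 0 || cfg$causalFraction > 1)
    stop("validation error: causalFraction must lie in (0, 1]")
  if (cfg$mediatorSpecificFraction < 0 || cfg$mediatorSpecificFraction > 1)
    stop("validation error: mediatorSpecificFraction must lie in [0, 1]")
  if (length(cfg$eafRange) != 2 || cfg$eafRange[1] <= 0 ||
      cfg$eafRange[2] >= 1 || cfg$eafRange[1] > cfg$eafRange[2])
    stop("validation error: eafRange must be an interval within (0, 1)")
  if (any(c(cfg$nExposure, cfg$nMediator, cfg$nOutcome) <= 0))
    stop("validation error: all sample sizes must be > 0")
  if (!is.null(cfg$ldBlockSizes) &&
      sum(cfg$ldBlockSizes) != cfg$nVariants)
    stop("validation error: ldBlockSizes must sum to nVariants")
  if (abs(cfg$ldWithinBlockR) > 1)
    stop("validation error: ldWithinBlockR must lie in [-1, 1]")
  invisible(cfg)
}

.gwasSe <- function(eaf, n) 1 / sqrt(2 * eaf * (1 - eaf) * n)

.makeGwas <- function(cfg, ids, chrom, pos, ea, oa, eaf, true_beta, n,
                      label, type, unit, noise) {
  se <- .gwasSe(eaf, n)
  beta <- true_beta + if (cfg$noiseless) 0 else noise * se
  GwasTable(data.frame(variant_id = ids, chromosome = chrom, position = pos,
                       effect_allele = ea, other_allele = oa, eaf = eaf,
                       beta = beta, se = se,
                       pvalue = pmax(2 * pnorm(-abs(beta / se)),
                                     .Machine$double.xmin),
                       n = n, stringsAsFactors = FALSE),
            traitLabel = label, traitType = type, unit = unit,
            checkPvalues = FALSE)
}

#' Simulate an exposure/mediator/outcome GWAS triplet with known truth
#'
#' Generates three summary-statistics tables sharing one variant panel and
#' allele coding, plus a block-diagonal LD matrix and the generating truth,
#' under the structural model described in [simulationConfig()]. Everything
#' is deterministic given `config$seed`.
#'
#' @param config a `SimulationConfig` from [simulationConfig()].
#' @return named list with elements `exposure`, `mediator`, `outcome`
#'   ([GwasTable-class]), `ld` ([LdMatrix-class]) and `truth`
#'   ([SimulationTruth-class]).
#' @export
simulateTriplet <- function(config) {
  .validateSimulationConfig(config)
  cfg <- config
  n <- cfg$nVariants
  set.seed(cfg$seed)
  ids <- sprintf("v%05d", seq_len(n))
  eaf <- runif(n, cfg$eafRange[1], cfg$eafRange[2])
  ea <- sample(.VALID_ALLELES, n, replace = TRUE)
  oa <- vapply(ea, function(a) sample(setdiff(.VALID_ALLELES, a), 1),
               character(1))
  causal <- runif(n) < cfg$causalFraction
  gamma <- ifelse(causal, rnorm(n, 0, cfg$gammaSd), 0)
  med_specific <- runif(n) < cfg$mediatorSpecificFraction
  delta <- if (cfg$deltaSd > 0)
    ifelse(med_specific, rnorm(n, 0, cfg$deltaSd), 0) else numeric(n)
  alpha <- switch(cfg$pleiotropyMode,
                  none = numeric(n),
                  balanced = rnorm(n, 0, cfg$alphaSd),
                  directional = rnorm(n, cfg$alphaMean, cfg$alphaSd))
  b_m <- cfg$thetaXM * gamma + delta
  b_y <- cfg$thetaDirect * gamma + cfg$thetaMY * b_m + alpha
  noise_x <- rnorm(n); noise_m <- rnorm(n); noise_y <- rnorm(n)
  chrom <- "1"
  pos <- seq_len(n) * 10000L

  exposure <- .makeGwas(cfg, ids, chrom, pos, ea, oa, eaf, gamma,
                        cfg$nExposure, "exposure", "continuous", "sd",
                        noise_x)
  mediator <- .makeGwas(cfg, ids, chrom, pos, ea, oa, eaf, b_m,
                        cfg$nMediator, "mediator", "continuous", "sd",
                        noise_m)
  outcome <- .makeGwas(cfg, ids, chrom, pos, ea, oa, eaf, b_y,
                       cfg$nOutcome,
                       "outcome", cfg$outcomeType,
                       if (cfg$outcomeType == "binary") "log-odds" else "sd",
                       noise_y)

  sizes <- if (is.null(cfg$ldBlockSizes)) rep(1L, n) else
    as.integer(cfg$ldBlockSizes)
  r <- matrix(0, n, n, dimnames = list(ids, ids))
  at <- 1L
  for (s in sizes) {
    idx <- at:(at + s - 1L)
    r[idx, idx] <- cfg$ldWithinBlockR
    at <- at + s
  }
  diag(r) <- 1

  theta_total <- cfg$thetaDirect + cfg$thetaXM * cfg$thetaMY
  truth <- new("SimulationTruth", gamma = gamma, delta = delta,
               alpha = alpha, thetaXM = cfg$thetaXM, thetaMY = cfg$thetaMY,
               thetaDirect = cfg$thetaDirect, thetaTotal = theta_total,
               proportionMediatedTrue =
                 if (theta_total != 0)
                   cfg$thetaXM * cfg$thetaMY / theta_total else NA_real_)

  list(exposure = exposure, mediator = mediator, outcome = outcome,
       ld = LdMatrix(r), truth = truth)
}

#' True per-variant effects for one trait of a simulated triplet
#'
#' @param truth a [SimulationTruth-class].
#' @param role which table's true effects to return.
#' @return numeric vector of true betas.
#' @export
trueBetas <- function(truth, role = c("exposure", "mediator", "outcome")) {
  role <- match.arg(role)
  b_m <- truth@thetaXM * truth@gamma + truth@delta
  switch(role,
         exposure = truth@gamma,
         mediator = b_m,
         outcome = truth@thetaDirect * truth@gamma +
           truth@thetaMY * b_m + truth@alpha)
}

#' Emulate winner's curse at a discovery threshold
#'
#' Replaces each variant's observed effect by a draw from a normal centred
#' on its true effect but truncated to the two-sided rejection region
#' `|beta| > z * se` of the discovery threshold, i.e. the distribution of
#' the estimate conditional on the variant having been discovered. Retained
#' variants therefore have stochastically inflated `|beta|`; far from the
#' significance boundary (|true beta|/se >> z) the truncation is negligible
#' and estimates are essentially unbiased. p-values are recomputed; a
#' threshold of 1 applies no selection and returns the table unchanged.
#'
#' @param table a [GwasTable-class] from [simulateTriplet()].
#' @param truth the matching [SimulationTruth-class].
#' @param discoveryThreshold p-value threshold of the discovery GWAS.
#' @param role which trait the table is (selects the true betas).
#' @param seed optional RNG seed.
#' @return a [GwasTable-class] of discovered variants.
#' @export
applyWinnersCurse <- function(table, truth, discoveryThreshold,
                              role = c("exposure", "mediator", "outcome"),
                              seed = NULL) {
  stopifnot(is(table, "GwasTable"), is(truth, "SimulationTruth"))
  if (discoveryThreshold <= 0 || discoveryThreshold > 1)
    stop("validation error: discoveryThreshold must lie in (0, 1]")
  role <- match.arg(role)
  mu <- trueBetas(truth, role)
  v <- table@variants
  if (length(mu) != nrow(v))
    stop("validation error: truth and table lengths differ")
  z <- qnorm(1 - discoveryThreshold / 2)
  if (z <= 0) return(table)
  if (!is.null(seed)) set.seed(seed)
  s <- v$se
  a <- z * s
  # tail masses of N(mu, s^2) beyond the +/- a boundary
  p_up <- pnorm((mu - a) / s)
  p_lo <- pnorm((-a - mu) / s)
  u <- runif(nrow(v))
  pick_up <- runif(nrow(v)) < p_up / (p_up + p_lo)
  # inverse-CDF draw within the chosen truncated tail
  lo_mass <- pnorm((-a - mu) / s)
  up_start <- pnorm((a - mu) / s)
  q <- ifelse(pick_up, up_start + u * (1 - up_start), u * lo_mass)
  beta <- mu + s * qnorm(q)
  v$beta <- beta
  v$pvalue <- pmax(2 * pnorm(-abs(beta / s)), .Machine$double.xmin)
  keep <- v$pvalue < discoveryThreshold
  v <- v[keep, , drop = FALSE]
  GwasTable(v, traitLabel = table@traitLabel, traitType = table@traitType,
            unit = table@unit, checkPvalues = FALSE)
}

#' Emulate collider distortion from heritable-covariable adjustment
#'
#' Shifts each observed exposure effect by
#' `-colliderStrength * covariableEffects[j]`, the first-order distortion a
#' GWAS adjusted for a heritable covariable (e.g. BMI in a blood-pressure
#' GWAS) induces in its per-variant estimates. The direction of the bias
#' this propagates into downstream MR estimates is unconstrained (toward or
#' away from the null), depending on how the covariable effects align with
#' the outcome pathway.
#'
#' @param table a [GwasTable-class].
#' @param colliderStrength scalar adjustment coefficient (0 = no change).
#' @param covariableEffects per-variant effects of the variants on the
#'   covariable; length must match the table.
#' @return the shifted [GwasTable-class].
#' @export
applyCovariableAdjustment <- function(table, colliderStrength,
                                      covariableEffects) {
  stopifnot(is(table, "GwasTable"))
  v <- table@variants
  if (length(covariableEffects) != nrow(v))
    stop("validation error: covariableEffects length (",
         length(covariableEffects), ") must match table (", nrow(v), ")")
  v$beta <- v$beta - colliderStrength * covariableEffects
  v$pvalue <- pmax(2 * pnorm(-abs(v$beta / v$se)), .Machine$double.xmin)
  GwasTable(v, traitLabel = table@traitLabel, traitType = table@traitType,
            unit = table@unit, checkPvalues = FALSE)
}
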