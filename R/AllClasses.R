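#' @import methods
#' @importFrom stats pnorm qnorm pchisq pt qt dnorm rnorm runif rbinom sd
#'   median quantile setNames complete.cases t.test
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

.VALID_ALLELES <- c("A", "C", "G", "T")

.GWAS_COLS <- c("variant_id", "chromosome", "position", "effect_allele",
                "other_allele", "eaf", "beta", "se", "pvalue", "n")

#' GwasTable: per-variant association summary statistics for one trait
#'
#' Holds one GWAS summary-statistics table: per variant, the effect and other
#' allele, effect-allele frequency, additive effect estimate (trait units per
#' effect-allele copy, or log-odds for binary traits), its standard error,
#' p-value and sample size. This is the unit every pipeline stage consumes.
#'
#' @slot traitLabel single string naming the trait.
#' @slot traitType `"continuous"` or `"binary"` (binary effects are on the
#'   log-odds scale).
#' @slot unit free-text unit of `beta` (e.g. `"mmHg"`, `"um"`, `"log-odds"`).
#' @slot variants `data.frame` with columns `variant_id`, `chromosome`,
#'   `position` (1-based), `effect_allele`, `other_allele`, `eaf`, `beta`,
#'   `se`, `pvalue`, `n`. `eaf` may be `NA` (frequency-based diagnostics are
#'   then unavailable); `position` is carried for interoperability only.
#'
#' @seealso [readGwasTable()], [simulateTriplet()]
#' @export
setClass("GwasTable",
  representation(traitLabel = "character",
                 traitType  = "character",
                 unit       = "character",
                 variants   = "data.frame"))

setValidity("GwasTable", function(object) {
  v <- object@variants
  msg <- character()
  if (length(object@traitLabel) != 1L) msg <- c(msg, "traitLabel must be a single string")
  if (!object@traitType %in% c("continuous", "binary"))
    msg <- c(msg, "traitType must be 'continuous' or 'binary'")
  missing_cols <- setdiff(.GWAS_COLS, names(v))
  if (length(missing_cols))
    return(paste0("variants lacks column(s): ", paste(missing_cols, collapse = ", ")))
  if (anyDuplicated(v$variant_id))
    msg <- c(msg, "variant_id must be unique within a table")
  bad_allele <- !(v$effect_allele %in% .VALID_ALLELES & v$other_allele %in% .VALID_ALLELES)
  if (any(bad_allele))
    msg <- c(msg, paste0("invalid allele code at row(s) ",
                         paste(utils::head(which(bad_allele), 5), collapse = ", ")))
  if (any(v$effect_allele == v$other_allele))
    msg <- c(msg, "effect_allele must differ from other_allele")
  if (any(!is.na(v$se) & v$se <= 0))
    msg <- c(msg, paste0("se must be > 0 (violated at row ",
                         which(!is.na(v$se) & v$se <= 0)[1], ")"))
  if (any(!is.na(v$eaf) & (v$eaf < 0 | v$eaf > 1)))
    msg <- c(msg, "eaf must lie in [0, 1]")
  if (any(!is.na(v$pvalue) & (v$pvalue <= 0 | v$pvalue > 1)))
    msg <- c(msg, "pvalue must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' LdMatrix: pairwise linkage-disequilibrium correlations
#'
#' Symmetric matrix of pairwise correlations (r, not r-squared) between
#' variants, with unit diagonal. Clumping squares these to r^2.
#'
#' @slot r square symmetric numeric matrix with variant ids as dimnames.
#' @seealso [readLdMatrix()], [ldClump()]
#' @export
setClass("LdMatrix", representation(r = "matrix"))

setValidity("LdMatrix", function(object) {
  r <- object@r
  msg <- character()
  if (nrow(r) != ncol(r)) return("LD matrix must be square")
  if (is.null(rownames(r)) || is.null(colnames(r)))
    return("LD matrix must carry variant ids as dimnames")
  if (!identical(rownames(r), colnames(r)))
    msg <- c(msg, "row and column variant ids must match")
  if (anyDuplicated(rownames(r))) msg <- c(msg, "variant ids must be unique")
  if (any(abs(r) > 1 + 1e-8)) msg <- c(msg, "|r| must not exceed 1")
  if (max(abs(r - t(r))) > 1e-8) msg <- c(msg, "matrix must be symmetric within 1e-8")
  if (max(abs(diag(r) - 1)) > 1e-8) msg <- c(msg, "diagonal must be 1")
  if (length(msg)) msg else TRUE
})

#' HarmonizedSet: exposure/outcome (and optionally mediator) effects on a
#' shared effect allele
#'
#' Result of aligning two or three summary-statistics tables to a common
#' effect allele per variant; the direct input of every causal estimator.
#'
#' @slot exposureLabel,outcomeLabel,mediatorLabel trait labels;
#'   `mediatorLabel` is `NA` for two-trait sets.
#' @slot variants `data.frame` with `variant_id`, `effect_allele`,
#'   `other_allele`, `beta_exposure`, `se_exposure`, `beta_mediator`,
#'   `se_mediator` (NA when no mediator), `beta_outcome`, `se_outcome`.
#' @slot nDroppedMismatch number of variants dropped because their allele
#'   pairs could not be reconciled by swap or strand complement.
#' @slot nFlipped number of variants whose outcome (or mediator) effect sign
#'   was flipped during alignment.
#' @seealso [harmonize()], [harmonizeMulti()]
#' @export
setClass("HarmonizedSet",
  representation(exposureLabel = "character",
                 outcomeLabel  = "character",
                 mediatorLabel = "character",
                 variants      = "data.frame",
                 nDroppedMismatch = "integer",
                 nFlipped      = "integer"))

setValidity("HarmonizedSet", function(object) {
  v <- object@variants
  need <- c("variant_id", "effect_allele", "other_allele",
            "beta_exposure", "se_exposure", "beta_mediator", "se_mediator",
            "beta_outcome", "se_outcome")
  missing_cols <- setdiff(need, names(v))
  if (length(missing_cols))
    return(paste0("variants lacks column(s): ", paste(missing_cols, collapse = ", ")))
  msg <- character()
  if (anyDuplicated(v$variant_id)) msg <- c(msg, "variant_id must be unique")
  if (any(v$se_exposure <= 0) || any(v$se_outcome <= 0) ||
      any(!is.na(v$se_mediator) & v$se_mediator <= 0))
    msg <- c(msg, "all standard errors must be > 0")
  if (length(msg)) msg else TRUE
})

#' MrResult: one causal-effect estimate with diagnostics
#'
#' @slot method one of `"wald"`, `"ivw"`, `"egger"`, `"weighted_median"`,
#'   `"contamination_mixture"`, `"presso_raw"`, `"presso_corrected"`,
#'   `"mvmr_direct"`.
#' @slot beta,se point estimate and standard error (se is `NA` for the
#'   contamination mixture, whose interval is profile-likelihood based).
#' @slot ciLow,ciHigh 95% confidence interval.
#' @slot pvalue two-sided p-value.
#' @slot nVariants number of variants used.
#' @slot scaleFactor exposure units per reported unit (1 until
#'   [transformEstimate()] is applied).
#' @slot oddsRatio whether beta/CI have been exponentiated to an odds-ratio
#'   scale (`se` then remains on the log scale).
#' @slot cochranQ,cochranQP heterogeneity statistic and p (NA where
#'   undefined).
#' @slot eggerIntercept,eggerInterceptSE,eggerInterceptP intercept test,
#'   populated by [mrEgger()] only.
#' @slot multimodal contamination-mixture flag: the 95% confidence set was a
#'   union of disjoint intervals and the reported CI is its enclosing hull.
#' @export
setClass("MrResult",
  representation(method = "character", beta = "numeric", se = "numeric",
                 ciLow = "numeric", ciHigh = "numeric", pvalue = "numeric",
                 nVariants = "integer", scaleFactor = "numeric",
                 oddsRatio = "logical",
                 cochranQ = "numeric", cochranQP = "numeric",
                 eggerIntercept = "numeric", eggerInterceptSE = "numeric",
                 eggerInterceptP = "numeric", multimodal = "logical"),
  prototype(scaleFactor = 1, oddsRatio = FALSE,
            cochranQ = NA_real_, cochranQP = NA_real_,
            eggerIntercept = NA_real_, eggerInterceptSE = NA_real_,
            eggerInterceptP = NA_real_, multimodal = FALSE))

setValidity("MrResult", function(object) {
  msg <- character()
  ok <- c("wald", "ivw", "egger", "weighted_median", "contamination_mixture",
          "presso_raw", "presso_corrected", "mvmr_direct")
  if (!object@method %in% ok)
    msg <- c(msg, paste0("unknown method '", object@method, "'"))
  if (!is.na(object@ciLow) && !is.na(object@ciHigh) && !is.na(object@beta)) {
    if (object@ciLow > object@beta + 1e-12 || object@ciHigh < object@beta - 1e-12)
      msg <- c(msg, "CI must bracket the point estimate")
  }
  if (!is.na(object@se) && object@se <= 0 && object@nVariants >= 2L)
    msg <- c(msg, "se must be > 0")
  if (length(msg)) msg else TRUE
})

#' PressoResult: MR-PRESSO global test, outlier flags and corrected estimate
#'
#' @slot globalP simulation-based p-value of the global heterogeneity
#'   (residual-sum-of-squares) test.
#' @slot outlierIds variant ids flagged by the Bonferroni-corrected
#'   per-variant outlier test.
#' @slot raw inverse-variance weighted estimate on all variants.
#' @slot corrected inverse-variance weighted estimate after removing flagged
#'   outliers (equal to `raw` when none are flagged).
#' @slot nSimulations,seed simulation settings used.
#' @export
setClass("PressoResult",
  representation(globalP = "numeric", outlierIds = "character",
                 raw = "MrResult", corrected = "MrResult",
                 nSimulations = "integer", seed = "integer"))

#' InstrumentDiagnostics: strength summaries of an instrument set
#'
#' @slot nInstruments number of instrumental variants.
#' @slot rSquared proportion of exposure variance explained by the set.
#' @slot fStatistic mean per-variant F statistic; values above 10 indicate
#'   low risk of weak-instrument bias.
#' @slot inverseF 1/F, the approximate relative magnitude of weak-instrument
#'   bias.
#' @slot perVariantF per-variant (beta/se)^2.
#' @export
setClass("InstrumentDiagnostics",
  representation(nInstruments = "integer", rSquared = "numeric",
                 fStatistic = "numeric", inverseF = "numeric",
                 perVariantF = "numeric"))

setValidity("InstrumentDiagnostics", function(object) {
  msg <- character()
  if (!is.na(object@rSquared) && (object@rSquared < 0 || object@rSquared > 1))
    msg <- c(msg, "rSquared must lie in [0, 1]")
  if (object@fStatistic > 0 &&
      abs(object@inverseF * object@fStatistic - 1) > 1e-8)
    msg <- c(msg, "inverseF must equal 1/fStatistic")
  if (length(msg)) msg else TRUE
})

#' MvmrResult: multivariable MR estimates (direct effects)
#'
#' Per-exposure coefficients from regressing variant-outcome effects jointly
#' on variant-exposure and variant-mediator effects; each coefficient is that
#' exposure's effect holding the other constant (the direct effect).
#'
#' @slot method `"mvmr_ivw"` or `"qhet"`.
#' @slot exposures exposure labels, in coefficient order.
#' @slot beta,se,ciLow,ciHigh,pvalue named per-exposure vectors.
#' @slot conditionalF named per-exposure conditional F statistics (NA when
#'   not computed).
#' @slot nVariants number of variants in the design.
#' @export
setClass("MvmrResult",
  representation(method = "character", exposures = "character",
                 beta = "numeric", se = "numeric",
                 ciLow = "numeric", ciHigh = "numeric", pvalue = "numeric",
                 conditionalF = "numeric", nVariants = "integer"))

setValidity("MvmrResult", function(object) {
  k <- length(object@exposures)
  if (any(lengths(list(object@beta, object@se, object@ciLow, object@ciHigh,
                       object@pvalue)) != k))
    return("per-exposure vectors must match length(exposures)")
  bad <- !is.na(object@ciLow) & !is.na(object@beta) &
    (object@ciLow > object@beta + 1e-12 | object@ciHigh < object@beta - 1e-12)
  if (any(bad)) return("CI must bracket the point estimate for every exposure")
  TRUE
})

#' MediationResult: total/direct/indirect decomposition
#'
#' @slot total univariable (total-effect) estimate.
#' @slot direct,directSE exposure's direct effect and se from multivariable
#'   MR.
#' @slot indirectDifference indirect effect by the difference method
#'   (total - direct), with CI: numeric `c(est, low, high)`.
#' @slot indirectProduct indirect effect by the product (network / two-step)
#'   method (theta_XM * theta_MY), with CI: numeric `c(est, low, high)`.
#' @slot proportionDifference,proportionProduct proportion mediated by each
#'   method, `c(est, low, high)`; negative values are legitimate when direct
#'   and indirect effects oppose.
#' @slot ciMethod `"delta"` or `"bootstrap"`.
#' @slot seed bootstrap seed (NA for delta).
#' @export
setClass("MediationResult",
  representation(total = "MrResult", direct = "numeric", directSE = "numeric",
                 indirectDifference = "numeric", indirectProduct = "numeric",
                 proportionDifference = "numeric", proportionProduct = "numeric",
                 ciMethod = "character", seed = "integer"))

setValidity("MediationResult", function(object) {
  if (abs(object@indirectDifference[1] -
          (object@total@beta - object@direct)) > 1e-12)
    return("indirectDifference must equal total - direct exactly")
  TRUE
})

#' SimulationTruth: the generating parameters behind a simulated triplet
#'
#' @slot gamma per-variant true variant-exposure effects.
#' @slot delta per-variant mediator-specific effects (variant-mediator
#'   effects not routed through the exposure).
#' @slot alpha per-variant horizontal-pleiotropy effects on the outcome.
#' @slot thetaXM,thetaMY,thetaDirect structural coefficients
#'   (exposure->mediator, mediator->outcome, exposure->outcome direct).
#' @slot thetaTotal `thetaDirect + thetaXM * thetaMY` (exact).
#' @slot proportionMediatedTrue `thetaXM * thetaMY / thetaTotal`.
#' @export
setClass("SimulationTruth",
  representation(gamma = "numeric", delta = "numeric", alpha = "numeric",
                 thetaXM = "numeric", thetaMY = "numeric",
                 thetaDirect = "numeric", thetaTotal = "numeric",
                 proportionMediatedTrue = "numeric"))

setValidity("SimulationTruth", function(object) {
  if (object@thetaTotal != object@thetaDirect + object@thetaXM * object@thetaMY)
    return("thetaTotal must equal thetaDirect + thetaXM * thetaMY exactly")
  TRUE
})

setClassUnion("GwasTableOrNULL", c("GwasTable", "NULL"))
setClassUnion("MediationResultOrNULL", c("MediationResult", "NULL"))
setClassUnion("PressoResultOrNULL", c("PressoResult", "NULL"))

#' StudyConfig: everything needed to run the full study design
#'
#' Built by [studyConfig()]; consumed by [runStudy()].
#'
#' @slot exposure,outcome,ld required inputs.
#' @slot mediator mediator table (enables the mediation arm).
#' @slot alternativeExposure covariable-unadjusted exposure table for the
#'   collider-bias rerun (optional).
#' @slot pThreshold,winnersCurseThreshold,clumpR2 selection thresholds.
#' @slot scaleFactor exposure units per reported unit (default 10).
#' @slot methods univariable methods to run.
#' @slot mediation whether to run the multivariable mediation arm.
#' @slot seed base seed for all stochastic components.
#' @export
setClass("StudyConfig",
  representation(exposure = "GwasTable", mediator = "GwasTableOrNULL",
                 outcome = "GwasTable", ld = "LdMatrix",
                 alternativeExposure = "GwasTableOrNULL",
                 pThreshold = "numeric", winnersCurseThreshold = "numeric",
                 clumpR2 = "numeric", scaleFactor = "numeric",
                 methods = "character", mediation = "logical",
                 seed = "integer"))

setValidity("StudyConfig", function(object) {
  msg <- character()
  for (s in c("pThreshold", "winnersCurseThreshold")) {
    v <- slot(object, s)
    if (v <= 0 || v >= 1) msg <- c(msg, paste0(s, " must lie in (0, 1)"))
  }
  if (object@clumpR2 <= 0 || object@clumpR2 > 1)
    msg <- c(msg, "clumpR2 must lie in (0, 1]")
  if (object@scaleFactor == 0) msg <- c(msg, "scaleFactor must be nonzero")
  if (length(msg)) msg else TRUE
})

#' StudyReport: full output of one study run
#'
#' @slot provenance config echo, seeds, package version, timestamps.
#' @slot instrumentDiagnostics [InstrumentDiagnostics] of the selected set.
#' @slot harmonization kept/flipped/dropped counts.
#' @slot results named list of [MrResult] (univariable battery, transformed
#'   to the reporting scale).
#' @slot presso [PressoResult] or `NULL`.
#' @slot mvmr named list of [MvmrResult] (`mvmr_ivw`, `qhet`) or empty.
#' @slot mediation [MediationResult] or `NULL`.
#' @slot reruns named list of sensitivity reruns (winner's-curse threshold,
#'   unadjusted exposure), each a named list of [MrResult].
#' @export
setClass("StudyReport",
  representation(provenance = "list",
                 instrumentDiagnostics = "InstrumentDiagnostics",
                 harmonization = "list",
                 results = "list",
                 presso = "PressoResultOrNULL",
                 mvmr = "list",
                 mediation = "MediationResultOrNULL",
                 reruns = "list"))
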