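#' Construct a GwasTable
#'
#' @param variants data.frame of per-variant summary statistics; missing
#'   optional columns (`chromosome`, `position`, `eaf`, `pvalue`, `n`) are
#'   filled with `NA`; a missing `pvalue` column is recomputed from `beta`
#'   and `se` under a two-sided normal test.
#' @param traitLabel,traitType,unit trait metadata.
#' @param checkPvalues if `TRUE`, warn (never reject) when a stored p-value
#'   disagrees with the two-sided normal p from `beta`/`se` by more than 10%
#'   relative.
#' @return a validated [GwasTable-class].
#' @export
GwasTable <- function(variants, traitLabel = "trait",
                      traitType = c("continuous", "binary"), unit = "",
                      checkPvalues = TRUE) {
  traitType <- match.arg(traitType)
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  for (col in c("chromosome", "position", "eaf", "pvalue", "n")) {
    if (is.null(variants[[col]])) {
      variants[[col]] <- if (col == "chromosome") NA_character_ else NA_real_
    }
  }
  required <- c("variant_id", "effect_allele", "other_allele", "beta", "se")
  miss <- setdiff(required, names(variants))
  if (length(miss))
    stop("format error: missing required column(s): ",
         paste(miss, collapse = ", "))
  bad_se <- which(!is.na(variants$se) & variants$se <= 0)
  if (length(bad_se))
    stop("validation error: non-positive se at row ", bad_se[1])
  variants$variant_id <- as.character(variants$variant_id)
  variants$chromosome <- as.character(variants$chromosome)
  variants$effect_allele <- toupper(as.character(variants$effect_allele))
  variants$other_allele <- toupper(as.character(variants$other_allele))
  pnormal <- 2 * pnorm(-abs(variants$beta / variants$se))
  need_p <- is.na(variants$pvalue)
  variants$pvalue[need_p] <- pmax(pnormal[need_p], .Machine$double.xmin)
  if (checkPvalues) {
    have <- !need_p & pnormal > 1e-300
    incons <- have & abs(variants$pvalue - pnormal) > 0.1 * pnormal
    if (any(incons))
      warning(sum(incons), " variant(s) have p-values inconsistent with ",
              "beta/se under a two-sided normal test (>10% relative); ",
              "first at row ", which(incons)[1])
  }
  variants <- variants[, .GWAS_COLS]
  rownames(variants) <- NULL
  new("GwasTable", traitLabel = traitLabel, traitType = traitType,
      unit = unit, variants = variants)
}

#' Construct an LdMatrix
#'
#' @param r square correlation matrix with variant ids as dimnames (or
#'   supplied via `variantIds`). Asymmetry up to 1e-8 is repaired by
#'   averaging; the diagonal is forced to 1.
#' @param variantIds optional character vector of ids.
#' @return a validated [LdMatrix-class].
#' @export
LdMatrix <- function(r, variantIds = NULL) {
  r <- as.matrix(r)
  if (nrow(r) != ncol(r)) stop("format error: LD matrix must be square")
  if (!is.null(variantIds)) dimnames(r) <- list(variantIds, variantIds)
  if (is.null(rownames(r)))
    stop("format error: LD matrix requires variant ids")
  if (any(abs(r) > 1 + 1e-8))
    stop("validation error: |r| exceeds 1")
  asym <- max(abs(r - t(r)))
  if (asym > 1e-8)
    stop("validation error: matrix asymmetric beyond 1e-8 (max ", signif(asym, 3), ")")
  r <- (r + t(r)) / 2
  diag(r) <- 1
  r[r > 1] <- 1
  r[r < -1] <- -1
  new("LdMatrix", r = r)
}

#' @rdname GwasTable
#' @param x,object a package object.
#' @export
setGeneric("variantIds", function(x) standardGeneric("variantIds"))

#' @rdname GwasTable
#' @export
setMethod("variantIds", "GwasTable", function(x) x@variants$variant_id)

#' @rdname GwasTable
#' @export
setMethod("variantIds", "LdMatrix", function(x) rownames(x@r))

#' @rdname GwasTable
#' @export
setMethod("variantIds", "HarmonizedSet", function(x) x@variants$variant_id)

#' @rdname GwasTable
#' @export
setGeneric("nVariants", function(x) standardGeneric("nVariants"))

#' @rdname GwasTable
#' @export
setMethod("nVariants", "GwasTable", function(x) nrow(x@variants))

#' @rdname GwasTable
#' @export
setMethod("nVariants", "HarmonizedSet", function(x) nrow(x@variants))

#' @rdname GwasTable
#' @export
setMethod("nVariants", "MrResult", function(x) x@nVariants)

#' @rdname GwasTable
#' @export
setGeneric("gwasData", function(x) standardGeneric("gwasData"))

#' @rdname GwasTable
#' @export
setMethod("gwasData", "GwasTable", function(x) x@variants)

#' @rdname GwasTable
#' @export
setGeneric("traitLabel", function(x) standardGeneric("traitLabel"))

#' @rdname GwasTable
#' @export
setMethod("traitLabel", "GwasTable", function(x) x@traitLabel)

#' @rdname GwasTable
#' @export
setGeneric("traitType", function(x) standardGeneric("traitType"))

#' @rdname GwasTable
#' @export
setMethod("traitType", "GwasTable", function(x) x@traitType)

#' Correlation matrix of an LdMatrix
#' @param x an [LdMatrix-class].
#' @return the symmetric correlation matrix (r, not squared).
#' @export
ldR <- function(x) x@r

#' Harmonized per-variant effects
#' @param x a [HarmonizedSet-class].
#' @return data.frame of aligned effects.
#' @export
harmonizedData <- function(x) x@variants

#' @rdname harmonizedData
#' @export
nDroppedMismatch <- function(x) x@nDroppedMismatch

#' Extract estimate fields from an MrResult
#' @param x an [MrResult-class] or [MvmrResult-class].
#' @return numeric estimate(s).
#' @export
setGeneric("mrBeta", function(x) standardGeneric("mrBeta"))

#' @rdname mrBeta
#' @export
setMethod("mrBeta", "MrResult", function(x) x@beta)

#' @rdname mrBeta
#' @export
setMethod("mrBeta", "MvmrResult", function(x) x@beta)

#' @rdname mrBeta
#' @export
setGeneric("mrSE", function(x) standardGeneric("mrSE"))

#' @rdname mrBeta
#' @export
setMethod("mrSE", "MrResult", function(x) x@se)

#' @rdname mrBeta
#' @export
setMethod("mrSE", "MvmrResult", function(x) x@se)

#' @rdname mrBeta
#' @export
setGeneric("mrCI", function(x) standardGeneric("mrCI"))

#' @rdname mrBeta
#' @export
setMethod("mrCI", "MrResult", function(x) c(low = x@ciLow, high = x@ciHigh))

#' @rdname mrBeta
#' @export
setGeneric("mrPvalue", function(x) standardGeneric("mrPvalue"))

#' @rdname mrBeta
#' @export
setMethod("mrPvalue", "MrResult", function(x) x@pvalue)

#' @rdname mrBeta
#' @export
setMethod("mrPvalue", "MvmrResult", function(x) x@pvalue)

#' @rdname mrBeta
#' @export
mrMethod <- function(x) x@method

#' Egger intercept test fields
#' @param x an [MrResult-class] produced by [mrEgger()].
#' @return named numeric: estimate, se, p.
#' @export
eggerIntercept <- function(x)
  c(estimate = x@eggerIntercept, se = x@eggerInterceptSE, p = x@eggerInterceptP)

#' MR-PRESSO accessors
#' @param x a [PressoResult-class].
#' @return the field value.
#' @export
pressoGlobalP <- function(x) x@globalP

#' @rdname pressoGlobalP
#' @export
pressoOutliers <- function(x) x@outlierIds

#' @rdname pressoGlobalP
#' @export
pressoRaw <- function(x) x@raw

#' @rdname pressoGlobalP
#' @export
pressoCorrected <- function(x) x@corrected

#' Conditional F statistics of an MVMR fit
#' @param x an [MvmrResult-class].
#' @return named per-exposure conditional F.
#' @export
conditionalFStats <- function(x) x@conditionalF

#' Mediation accessors
#' @param x a [MediationResult-class].
#' @param method `"difference"` (MVMR) or `"product"` (network / two-step).
#' @return `c(estimate, ci_low, ci_high)`.
#' @export
indirectEffect <- function(x, method = c("difference", "product")) {
  method <- match.arg(method)
  if (method == "difference") x@indirectDifference else x@indirectProduct
}

#' @rdname indirectEffect
#' @export
proportionMediated <- function(x, method = c("difference", "product")) {
  method <- match.arg(method)
  if (method == "difference") x@proportionDifference else x@proportionProduct
}

#' Simulation-truth accessors
#' @param x a [SimulationTruth-class].
#' @return the stored generating value(s).
#' @export
trueTheta <- function(x)
  c(total = x@thetaTotal, direct = x@thetaDirect,
    xm = x@thetaXM, my = x@thetaMY)

#' @rdname trueTheta
#' @export
trueProportionMediated <- function(x) x@proportionMediatedTrue

#' @rdname trueTheta
#' @export
trueGamma <- function(x) x@gamma

#' @rdname trueTheta
#' @export
trueAlpha <- function(x) x@alpha

#' @rdname trueTheta
#' @export
trueDelta <- function(x) x@delta

setMethod("show", "GwasTable", function(object) {
  cat("GwasTable '", object@traitLabel, "' (", object@traitType,
      if (nzchar(object@unit)) paste0(", ", object@unit), ")\n",
      "  ", nrow(object@variants), " variants\n", sep = "")
  print(utils::head(object@variants, 4))
  if (nrow(object@variants) > 4) cat("  ...\n")
})

setMethod("show", "LdMatrix", function(object) {
  cat("LdMatrix: ", nrow(object@r), " x ", ncol(object@r), " variants\n",
      sep = "")
})

setMethod("show", "HarmonizedSet", function(object) {
  cat("HarmonizedSet: ", object@exposureLabel,
      if (!is.na(object@mediatorLabel)) paste0(" + ", object@mediatorLabel),
      " -> ", object@outcomeLabel, "\n",
      "  ", nrow(object@variants), " variants (", object@nFlipped,
      " sign-flipped, ", object@nDroppedMismatch, " dropped as mismatch)\n",
      sep = "")
})

setMethod("show", "MrResult", function(object) {
  lab <- if (object@oddsRatio) "OR" else "beta"
  cat(sprintf("MrResult [%s] %s = %.4g (95%% CI %.4g to %.4g), p = %.3g, k = %d\n",
              object@method, lab, object@beta, object@ciLow, object@ciHigh,
              object@pvalue, object@nVariants))
  if (!is.na(object@eggerIntercept))
    cat(sprintf("  intercept = %.4g (p = %.3g)\n",
                object@eggerIntercept, object@eggerInterceptP))
  if (!is.na(object@cochranQ))
    cat(sprintf("  Cochran Q = %.3g (p = %.3g)\n",
                object@cochranQ, object@cochranQP))
})

setMethod("show", "PressoResult", function(object) {
  cat(sprintf("PressoResult: global p = %.4g, %d outlier(s) flagged\n",
              object@globalP, length(object@outlierIds)))
  cat(sprintf("  raw       beta = %.4g\n", object@raw@beta))
  cat(sprintf("  corrected beta = %.4g (k = %d)\n",
              object@corrected@beta, object@corrected@nVariants))
})

setMethod("show", "InstrumentDiagnostics", function(object) {
  cat(sprintf(
    "InstrumentDiagnostics: %d variants, R^2 = %.4g, F = %.4g, 1/F = %.4g\n",
    object@nInstruments, object@rSquared, object@fStatistic, object@inverseF))
})

setMethod("show", "MvmrResult", function(object) {
  cat("MvmrResult [", object@method, "], k = ", object@nVariants,
      " variants\n", sep = "")
  tab <- data.frame(exposure = object@exposures, beta = object@beta,
                    se = object@se, ci_low = object@ciLow,
                    ci_high = object@ciHigh, p = object@pvalue,
                    conditional_F = object@conditionalF)
  print(tab, row.names = FALSE, digits = 4)
})

setMethod("show", "MediationResult", function(object) {
  cat("MediationResult (CI method: ", object@ciMethod, ")\n", sep = "")
  cat(sprintf("  total     = %.4g\n", object@total@beta))
  cat(sprintf("  direct    = %.4g (se %.4g)\n", object@direct, object@directSE))
  cat(sprintf("  indirect  difference = %.4g (%.4g, %.4g)\n",
              object@indirectDifference[1], object@indirectDifference[2],
              object@indirectDifference[3]))
  cat(sprintf("  indirect  product    = %.4g (%.4g, %.4g)\n",
              object@indirectProduct[1], object@indirectProduct[2],
              object@indirectProduct[3]))
  cat(sprintf("  prop. mediated (difference) = %.3g (%.3g, %.3g)\n",
              object@proportionDifference[1], object@proportionDifference[2],
              object@proportionDifference[3]))
  cat(sprintf("  prop. mediated (product)    = %.3g (%.3g, %.3g)\n",
              object@proportionProduct[1], object@proportionProduct[2],
              object@proportionProduct[3]))
})

setMethod("show", "SimulationTruth", function(object) {
  cat(sprintf(
    "SimulationTruth: theta_total = %.4g (direct %.4g + %.4g x %.4g), PM = %.3g\n",
    object@thetaTotal, object@thetaDirect, object@thetaXM, object@thetaMY,
    object@proportionMediatedTrue))
})

setMethod("show", "StudyReport", function(object) {
  cat("StudyReport:", object@provenance$exposure_label, "->",
      object@provenance$outcome_label, "\n")
  show(object@instrumentDiagnostics)
  for (r in object@results) show(r)
  if (!is.null(object@presso)) show(object@presso)
  if (!is.null(object@mediation)) show(object@mediation)
})
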