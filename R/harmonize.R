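.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

.isPalindromic <- function(ea, oa) .COMPLEMENT[ea] == oa

# Align one record's (ea2, oa2) to the reference pair (ea, oa).
# Returns +1 (already aligned), -1 (effect sign must flip) or NA
# (irreconcilable). Non-palindromic pairs may additionally match through a
# strand complement; palindromic (A/T, C/G) pairs are aligned by nominal
# labels only, with no strand or frequency inference.
.alignAlleles <- function(ea, oa, ea2, oa2) {
  if (ea2 == ea && oa2 == oa) return(1)
  if (ea2 == oa && oa2 == ea) return(-1)
  if (!.isPalindromic(ea, oa)) {
    cea <- .COMPLEMENT[[ea2]]; coa <- .COMPLEMENT[[oa2]]
    if (cea == ea && coa == oa) return(1)
    if (cea == oa && coa == ea) return(-1)
  }
  NA_real_
}

.alignTable <- function(ref, other) {
  # ref, other: variant data.frames already matched/ordered on variant_id
  n <- nrow(ref)
  sign <- numeric(n)
  for (i in seq_len(n)) {
    sign[i] <- .alignAlleles(ref$effect_allele[i], ref$other_allele[i],
                             other$effect_allele[i], other$other_allele[i])
  }
  sign
}

#' Harmonize exposure and outcome summary statistics
#'
#' Intersects two tables on variant id and aligns the outcome's effects to
#' the exposure's effect allele. Where the outcome's alleles are swapped
#' relative to the exposure's, the outcome beta sign is flipped (and its
#' eaf reflected); non-palindromic pairs may also be reconciled through a
#' strand complement. Palindromic (A/T, C/G) variants are retained and
#' aligned by their nominal allele labels, with no strand inference and no
#' exclusions. Variants whose allele pairs cannot be reconciled are dropped
#' and counted.
#'
#' @param exposure,outcome [GwasTable-class] objects.
#' @return a [HarmonizedSet-class] (mediator columns `NA`).
#' @export
harmonize <- function(exposure, outcome) {
  stopifnot(is(exposure, "GwasTable"), is(outcome, "GwasTable"))
  ex <- exposure@variants
  ou <- outcome@variants
  common <- intersect(ex$variant_id, ou$variant_id)
  if (length(common) == 0)
    stop("validation error: no shared variants between exposure and outcome")
  ex <- ex[match(common, ex$variant_id), , drop = FALSE]
  ex <- ex[order(match(ex$variant_id, exposure@variants$variant_id)), ,
           drop = FALSE]
  ou <- ou[match(ex$variant_id, ou$variant_id), , drop = FALSE]
  sgn <- .alignTable(ex, ou)
  keep <- !is.na(sgn)
  v <- data.frame(variant_id = ex$variant_id[keep],
                  effect_allele = ex$effect_allele[keep],
                  other_allele = ex$other_allele[keep],
                  beta_exposure = ex$beta[keep],
                  se_exposure = ex$se[keep],
                  beta_mediator = rep(NA_real_, sum(keep)),
                  se_mediator = rep(NA_real_, sum(keep)),
                  beta_outcome = sgn[keep] * ou$beta[keep],
                  se_outcome = ou$se[keep],
                  stringsAsFactors = FALSE)
  rownames(v) <- NULL
  new("HarmonizedSet", exposureLabel = exposure@traitLabel,
      outcomeLabel = outcome@traitLabel, mediatorLabel = NA_character_,
      variants = v, nDroppedMismatch = sum(!keep),
      nFlipped = sum(sgn[keep] < 0))
}

#' Harmonize exposure, mediator and outcome to a shared effect allele
#'
#' Three-way intersection restricted to an instrument list, with mediator
#' and outcome effects each aligned to the exposure's effect alleles using
#' the same swap/complement/drop semantics as [harmonize()]. A variant is
#' dropped (and counted) if either alignment fails or if it is absent from
#' any of the three tables.
#'
#' @param exposure,mediator,outcome [GwasTable-class] objects.
#' @param instrumentUnion a [GwasTable-class] (or character vector of
#'   variant ids) giving the joint instrument list; see
#'   [unionInstruments()].
#' @return a [HarmonizedSet-class] with mediator columns populated.
#' @export
harmonizeMulti <- function(exposure, mediator, outcome, instrumentUnion) {
  stopifnot(is(exposure, "GwasTable"), is(mediator, "GwasTable"),
            is(outcome, "GwasTable"))
  ids <- if (is.character(instrumentUnion)) instrumentUnion
         else variantIds(instrumentUnion)
  ex <- exposure@variants
  me <- mediator@variants
  ou <- outcome@variants
  common <- Reduce(intersect, list(ids, ex$variant_id, me$variant_id,
                                   ou$variant_id))
  n_absent <- length(ids) - length(common)
  if (length(common) == 0)
    stop("validation error: no shared variants across the three tables")
  ex <- ex[match(common, ex$variant_id), , drop = FALSE]
  me <- me[match(common, me$variant_id), , drop = FALSE]
  ou <- ou[match(common, ou$variant_id), , drop = FALSE]
  sgn_m <- .alignTable(ex, me)
  sgn_o <- .alignTable(ex, ou)
  keep <- !is.na(sgn_m) & !is.na(sgn_o)
  v <- data.frame(variant_id = ex$variant_id[keep],
                  effect_allele = ex$effect_allele[keep],
                  other_allele = ex$other_allele[keep],
                  beta_exposure = ex$beta[keep],
                  se_exposure = ex$se[keep],
                  beta_mediator = sgn_m[keep] * me$beta[keep],
                  se_mediator = me$se[keep],
                  beta_outcome = sgn_o[keep] * ou$beta[keep],
                  se_outcome = ou$se[keep],
                  stringsAsFactors = FALSE)
  rownames(v) <- NULL
  new("HarmonizedSet", exposureLabel = exposure@traitLabel,
      outcomeLabel = outcome@traitLabel, mediatorLabel = mediator@traitLabel,
      variants = v,
      nDroppedMismatch = as.integer(sum(!keep) + n_absent),
      nFlipped = as.integer(sum(sgn_m[keep] < 0 | sgn_o[keep] < 0)))
}

#' Build the joint instrument list for multivariable MR
#'
#' Union of the independently selected and clumped exposure and mediator
#' instruments, re-clumped jointly at the same r^2 threshold (each
#' variant's priority p-value is the smaller of its p-values in the tables
#' that contributed it; ties broken as in [ldClump()]). Both exposures need
#' relevance in the joint design, hence the union convention.
#'
#' @param exposure,mediator full [GwasTable-class] objects.
#' @param ld an [LdMatrix-class] covering both instrument sets.
#' @param pThreshold,r2Threshold selection settings (see
#'   [selectByPvalue()], [ldClump()]).
#' @return a [GwasTable-class] of jointly clumped instruments (beta/se/p
#'   taken from the contributing table with the smaller p).
#' @export
unionInstruments <- function(exposure, mediator, ld, pThreshold = 5e-8,
                             r2Threshold = 0.01) {
  ins_x <- ldClump(selectByPvalue(exposure, pThreshold), ld, r2Threshold)
  ins_m <- ldClump(selectByPvalue(mediator, pThreshold), ld, r2Threshold)
  vx <- ins_x@variants
  vm <- ins_m@variants
  both <- rbind(vx, vm)
  both <- both[order(both$pvalue), , drop = FALSE]
  both <- both[!duplicated(both$variant_id), , drop = FALSE]
  pooled <- GwasTable(both, traitLabel = "instrument_union",
                      traitType = "continuous", unit = "",
                      checkPvalues = FALSE)
  ldClump(pooled, ld, r2Threshold)
}
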