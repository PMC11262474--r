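#' Select variants below a p-value threshold
#'
#' Retains exactly the records with `pvalue` strictly below `threshold`,
#' preserving input order. The filter is monotone: lowering the threshold
#' can only shrink the selected set.
#'
#' @param table a [GwasTable-class].
#' @param threshold p-value threshold in (0, 1]; genome-wide significance is
#'   `5e-8`, the winner's-curse-robust rerun uses `1e-11`.
#' @return the filtered [GwasTable-class].
#' @export
selectByPvalue <- function(table, threshold = 5e-8) {
  stopifnot(is(table, "GwasTable"))
  if (threshold <= 0 || threshold > 1)
    stop("validation error: threshold must lie in (0, 1]")
  v <- table@variants
  keep <- !is.na(v$pvalue) & v$pvalue < threshold
  GwasTable(v[keep, , drop = FALSE], traitLabel = table@traitLabel,
            traitType = table@traitType, unit = table@unit,
            checkPvalues = FALSE)
}

# Deterministic clumping priority: smallest p first; ties broken by |z|
# descending, then variant_id lexicographic, so output is invariant to
# input row order.
.clumpOrder <- function(v) {
  order(v$pvalue, -abs(v$beta / v$se), v$variant_id)
}

#' Greedy LD clumping
#'
#' Repeatedly takes the remaining variant with the smallest p-value as an
#' index and discards every remaining variant in LD with it at
#' `r^2 >= r2Threshold`; the retained index variants are pairwise below the
#' threshold. p-value ties are broken by |beta|/se descending, then by
#' variant id, so the result does not depend on input row order.
#'
#' @param table a [GwasTable-class] (typically already p-value selected).
#' @param ld an [LdMatrix-class] covering every variant in `table`.
#' @param r2Threshold squared-correlation threshold in (0, 1]; the study
#'   default is 0.01.
#' @return the clumped [GwasTable-class], in index-selection order.
#' @export
ldClump <- function(table, ld, r2Threshold = 0.01) {
  stopifnot(is(table, "GwasTable"), is(ld, "LdMatrix"))
  if (r2Threshold <= 0 || r2Threshold > 1)
    stop("validation error: r2Threshold must lie in (0, 1]")
  v <- table@variants
  missing <- setdiff(v$variant_id, rownames(ld@r))
  if (length(missing))
    stop("lookup error: variant(s) absent from LD matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  if (nrow(v) == 0)
    return(table)
  v <- v[.clumpOrder(v), , drop = FALSE]
  r2 <- ld@r[v$variant_id, v$variant_id, drop = FALSE]^2
  alive <- rep(TRUE, nrow(v))
  keep <- logical(nrow(v))
  for (i in seq_len(nrow(v))) {
    if (!alive[i]) next
    keep[i] <- TRUE
    hit <- alive & r2[i, ] >= r2Threshold
    alive[hit] <- FALSE
  }
  GwasTable(v[keep, , drop = FALSE], traitLabel = table@traitLabel,
            traitType = table@traitType, unit = table@unit,
            checkPvalues = FALSE)
}

#' Instrument-strength diagnostics
#'
#' Per-variant F statistics `F_j = (beta_j / se_j)^2`, their mean (the
#' reported F statistic; values above 10 indicate low risk of
#' weak-instrument bias), `1/F` (the approximate relative magnitude of any
#' weak-instrument bias) and the proportion of exposure variance explained.
#'
#' Two R^2 conventions are offered: `"f"` (default) sums the per-variant
#' variance-explained approximation `F_j / (F_j + n_j - 2)` and needs no
#' allele frequencies; `"eaf"` sums `2 f_j (1 - f_j) beta_j^2`, which
#' assumes a variance-standardized trait and requires `eaf`.
#'
#' @param table a [GwasTable-class] of selected instruments (nonempty, with
#'   `n` available for the `"f"` method).
#' @param r2Method `"f"` or `"eaf"`.
#' @return an [InstrumentDiagnostics-class].
#' @export
instrumentStrength <- function(table, r2Method = c("f", "eaf")) {
  stopifnot(is(table, "GwasTable"))
  r2Method <- match.arg(r2Method)
  v <- table@variants
  if (nrow(v) == 0)
    stop("validation error: empty instrument set")
  f <- (v$beta / v$se)^2
  names(f) <- v$variant_id
  r2 <- switch(r2Method,
    f = {
      if (anyNA(v$n))
        stop("validation error: sample size n required for the F-based R^2")
      sum(f / (f + v$n - 2))
    },
    eaf = {
      if (anyNA(v$eaf))
        stop("validation error: eaf required for the frequency-based R^2")
      sum(2 * v$eaf * (1 - v$eaf) * v$beta^2)
    })
  fbar <- mean(f)
  new("InstrumentDiagnostics", nInstruments = nrow(v),
      rSquared = min(r2, 1), fStatistic = fbar,
      inverseF = if (fbar > 0) 1 / fbar else Inf, perVariantF = f)
}
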