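#' Build a study configuration
#'
#' @param exposure,outcome,ld required [GwasTable-class] /
#'   [LdMatrix-class] inputs.
#' @param mediator optional mediator [GwasTable-class]; supplying it with
#'   `mediation = TRUE` enables the multivariable mediation arm.
#' @param alternativeExposure optional covariable-unadjusted exposure table
#'   for the collider-bias rerun.
#' @param pThreshold instrument p-value threshold (default genome-wide,
#'   5e-8).
#' @param winnersCurseThreshold stricter threshold for the winner's-curse
#'   rerun (default 1e-11).
#' @param clumpR2 LD clumping threshold on r^2 (default 0.01).
#' @param scaleFactor exposure units per reported unit (default 10, e.g.
#'   per 10 mmHg).
#' @param methods univariable methods to run.
#' @param mediation run the mediation arm (requires `mediator`).
#' @param seed base seed for all stochastic components.
#' @return a validated [StudyConfig-class].
#' @export
studyConfig <- function(exposure, outcome, ld, mediator = NULL,
                        alternativeExposure = NULL, pThreshold = 5e-8,
                        winnersCurseThreshold = 1e-11, clumpR2 = 0.01,
                        scaleFactor = 10,
                        methods = c("ivw", "egger", "weighted_median",
                                    "contamination_mixture", "mr_presso"),
                        mediation = !is.null(mediator), seed = 1L) {
  new("StudyConfig", exposure = exposure, mediator = mediator,
      outcome = outcome, ld = ld,
      alternativeExposure = alternativeExposure,
      pThreshold = pThreshold,
      winnersCurseThreshold = winnersCurseThreshold, clumpR2 = clumpR2,
      scaleFactor = scaleFactor, methods = methods,
      mediation = isTRUE(mediation) && !is.null(mediator),
      seed = as.integer(seed))
}

.runBattery <- function(h, methods, scaleFactor, asOR, seed) {
  out <- list()
  scale1 <- function(r) transformEstimate(r, scaleFactor, asOR)
  if ("ivw" %in% methods) out$ivw <- scale1(mrIvw(h))
  if ("egger" %in% methods && nVariants(h) >= 3)
    out$egger <- scale1(mrEgger(h))
  if ("weighted_median" %in% methods && nVariants(h) >= 3)
    out$weighted_median <- scale1(mrWeightedMedian(h, seed = seed))
  if ("contamination_mixture" %in% methods && nVariants(h) >= 3)
    out$contamination_mixture <- scale1(mrConMix(h))
  out
}

.stageWrap <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("[stage: ", stage, "] ", conditionMessage(e), call. = FALSE))
}

#' Run the full study design
#'
#' Executes instrument selection (p-value threshold, then greedy LD
#' clumping), harmonization, the univariable estimator battery with its
#' pleiotropy diagnostics, optionally the multivariable mediation arm
#' (joint instrument union, MVMR-IVW with conditional F, Qhet sensitivity
#' fit, total/direct/indirect decomposition), and the sensitivity reruns
#' (stricter winner's-curse instrument threshold; covariable-unadjusted
#' exposure table when provided). Binary outcomes are reported as odds
#' ratios. Deterministic given `config@seed`.
#'
#' @param config a [StudyConfig-class].
#' @return a [StudyReport-class].
#' @export
runStudy <- function(config) {
  stopifnot(is(config, "StudyConfig"))
  validObject(config)
  seed <- config@seed
  asOR <- traitType(config@outcome) == "binary"

  instruments <- .stageWrap("instrument_selection", {
    sel <- selectByPvalue(config@exposure, config@pThreshold)
    ldClump(sel, config@ld, config@clumpR2)
  })
  diagnostics <- .stageWrap("instrument_diagnostics",
                            instrumentStrength(instruments))
  h <- .stageWrap("harmonization", harmonize(instruments, config@outcome))
  harm_counts <- list(n_selected = nVariants(instruments),
                      n_harmonized = nVariants(h),
                      n_flipped = h@nFlipped,
                      n_dropped_mismatch = h@nDroppedMismatch)

  results <- .stageWrap("univariable_mr",
                        .runBattery(h, config@methods, config@scaleFactor,
                                    asOR, seed))
  presso <- NULL
  if ("mr_presso" %in% config@methods && nVariants(h) >= 4) {
    presso <- .stageWrap("mr_presso", {
      p <- mrPresso(h, seed = seed)
      p@raw <- transformEstimate(p@raw, config@scaleFactor, asOR)
      p@corrected <- transformEstimate(p@corrected, config@scaleFactor, asOR)
      p
    })
  }

  mvmr <- list()
  mediation <- NULL
  if (config@mediation) {
    med <- .stageWrap("mediation", {
      uni <- unionInstruments(config@exposure, config@mediator, config@ld,
                              config@pThreshold, config@clumpR2)
      h3 <- harmonizeMulti(config@exposure, config@mediator,
                           config@outcome, uni)
      fit <- mvmrIvw(h3)
      qhet <- qhetMvmr(h3, seed = seed)
      hx2m <- harmonize(instruments, config@mediator)
      theta_xm <- mrIvw(hx2m)
      total_raw <- mrIvw(h)
      dec <- decomposeMediation(total_raw, fit, theta_xm,
                                ciMethod = "bootstrap", seed = seed)
      list(fit = fit, qhet = qhet, dec = dec)
    })
    mvmr <- list(mvmr_ivw = med$fit, qhet = med$qhet)
    mediation <- med$dec
  }

  reruns <- list()
  reruns$winners_curse <- .stageWrap("winners_curse_rerun", {
    sel <- selectByPvalue(config@exposure, config@winnersCurseThreshold)
    if (nVariants(sel) >= 1) {
      ins <- ldClump(sel, config@ld, config@clumpR2)
      hh <- harmonize(ins, config@outcome)
      list(ivw = transformEstimate(mrIvw(hh), config@scaleFactor, asOR))
    } else list()
  })
  if (!is.null(config@alternativeExposure)) {
    reruns$unadjusted_exposure <- .stageWrap("collider_rerun", {
      sel <- selectByPvalue(config@alternativeExposure, config@pThreshold)
      ins <- ldClump(sel, config@ld, config@clumpR2)
      hh <- harmonize(ins, config@outcome)
      list(ivw = transformEstimate(mrIvw(hh), config@scaleFactor, asOR))
    })
  }

  provenance <- list(
    package = "mrmediate",
    version = as.character(utils::packageVersion("mrmediate")),
    exposure_label = traitLabel(config@exposure),
    outcome_label = traitLabel(config@outcome),
    mediator_label = if (!is.null(config@mediator))
      traitLabel(config@mediator) else NA,
    outcome_type = traitType(config@outcome),
    p_threshold = config@pThreshold,
    winners_curse_threshold = config@winnersCurseThreshold,
    clump_r2 = config@clumpR2,
    scale_factor = config@scaleFactor,
    odds_ratio = asOR,
    methods = as.list(config@methods),
    mediation = config@mediation,
    seed = seed)

  new("StudyReport", provenance = provenance,
      instrumentDiagnostics = diagnostics, harmonization = harm_counts,
      results = results, presso = presso, mvmr = mvmr,
      mediation = mediation, reruns = reruns)
}

#' Compare a primary study run with a sensitivity rerun
#'
#' Tabulates, per shared method, the two estimates, their difference in
#' units of the combined standard error, and consistency flags (same sign;
#' overlapping 95% CIs).
#'
#' @param primary,rerun [StudyReport-class] objects for the same
#'   exposure/outcome pair.
#' @return data.frame with one row per shared method.
#' @export
compareReruns <- function(primary, rerun) {
  stopifnot(is(primary, "StudyReport"), is(rerun, "StudyReport"))
  if (!identical(primary@provenance$exposure_label,
                 rerun@provenance$exposure_label) ||
      !identical(primary@provenance$outcome_label,
                 rerun@provenance$outcome_label))
    stop("validation error: reports are for different exposure/outcome ",
         "pairs")
  shared <- intersect(names(primary@results), names(rerun@results))
  rows <- lapply(shared, function(m) {
    a <- primary@results[[m]]
    b <- rerun@results[[m]]
    comb_se <- sqrt(a@se^2 + b@se^2)
    data.frame(method = m, beta_primary = a@beta, beta_rerun = b@beta,
               diff_in_se = if (is.finite(comb_se) && comb_se > 0)
                 (a@beta - b@beta) / comb_se else NA_real_,
               same_sign = sign(a@beta) == sign(b@beta),
               ci_overlap = a@ciLow <= b@ciHigh && b@ciLow <= a@ciHigh)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
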