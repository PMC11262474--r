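# Column alias table for external GWAS summary-statistics dialects.
# Matching is case-insensitive; two file columns resolving to the same
# canonical name is an error, never a guess (mis-mapped alleles would
# silently corrupt harmonization).
.COLUMN_ALIASES <- list(
  variant_id    = c("variant_id", "snp", "rsid", "rs_id", "id", "markername"),
  chromosome    = c("chromosome", "chr", "chrom", "#chr", "#chrom"),
  position      = c("position", "pos", "bp", "base_pair_location"),
  effect_allele = c("effect_allele", "ea", "a1", "allele1", "alt",
                    "tested_allele"),
  other_allele  = c("other_allele", "oa", "a2", "allele2", "nea", "ref",
                    "noneffect_allele"),
  eaf           = c("eaf", "effect_allele_frequency", "freq", "freq1", "af",
                    "a1freq"),
  beta          = c("beta", "b", "effect", "beta_hat"),
  se            = c("se", "standard_error", "stderr", "sebeta"),
  pvalue        = c("pvalue", "p", "pval", "p_value", "p-value", "p_bolt_lmm"),
  n             = c("n", "samplesize", "sample_size", "n_total", "neff")
)

.resolveColumns <- function(found, column_map = NULL) {
  aliases <- .COLUMN_ALIASES
  if (!is.null(column_map)) {
    for (canon in names(column_map))
      aliases[[canon]] <- unique(c(column_map[[canon]], aliases[[canon]]))
  }
  lower <- tolower(found)
  out <- character()
  for (canon in names(aliases)) {
    hits <- which(lower %in% tolower(aliases[[canon]]))
    if (length(hits) > 1)
      stop("format error: columns ", paste(found[hits], collapse = ", "),
           " are ambiguous for '", canon, "'")
    if (length(hits) == 1) out[[canon]] <- found[hits]
  }
  out
}

#' Read a GWAS summary-statistics table
#'
#' Reads a tab-delimited (optionally gzip-compressed) table of per-variant
#' associations. Column names are matched case-insensitively against an
#' alias table covering common GWAS export dialects (`SNP`/`rsid`,
#' `A1`/`effect_allele`, `A2`/`other_allele`, ...); ambiguity is an error.
#' Required: variant id, both alleles, beta, se. Optional: chromosome,
#' position, eaf, pvalue (recomputed from beta/se when absent), n.
#'
#' @param path file path.
#' @param column_map optional named list adding file-specific aliases, e.g.
#'   `list(variant_id = "my_snp_col")`.
#' @param traitLabel,traitType,unit trait metadata (see [GwasTable()]).
#' @return a [GwasTable-class].
#' @export
readGwasTable <- function(path, column_map = NULL, traitLabel = NULL,
                          traitType = c("continuous", "binary"), unit = "") {
  if (!file.exists(path)) stop("I/O error: no such file: ", path)
  traitType <- match.arg(traitType)
  raw <- data.table::fread(path, sep = "\t", header = TRUE,
                           data.table = FALSE, showProgress = FALSE)
  res <- .resolveColumns(names(raw), column_map)
  required <- c("variant_id", "effect_allele", "other_allele", "beta", "se")
  miss <- setdiff(required, names(res))
  if (length(miss))
    stop("format error: missing required column(s): ",
         paste(miss, collapse = ", "))
  dat <- raw[, unname(res), drop = FALSE]
  names(dat) <- names(res)
  if (is.null(traitLabel))
    traitLabel <- sub("\\.(tsv|txt)(\\.gz)?$", "", basename(path))
  GwasTable(dat, traitLabel = traitLabel, traitType = traitType, unit = unit)
}

#' Write a GWAS summary-statistics table
#'
#' Canonical tab-delimited dialect: header row with columns `variant_id`,
#' `chromosome`, `position`, `effect_allele`, `other_allele`, `eaf`, `beta`,
#' `se`, `pvalue`, `n`. Full double precision is preserved, so
#' write-then-read round-trips are exact.
#'
#' @param table a [GwasTable-class].
#' @param path destination path (`.gz` suffix writes gzip).
#' @return invisibly, `path`.
#' @export
writeGwasTable <- function(table, path) {
  stopifnot(is(table, "GwasTable"))
  v <- table@variants
  num <- vapply(v, is.numeric, logical(1))
  v[num] <- lapply(v[num], function(x) sprintf("%.17g", x))
  v[v == "nan" | v == "NA"] <- "NA"
  data.table::fwrite(v, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' Read an LD matrix
#'
#' Tab-delimited square matrix of pairwise correlations; the first row and
#' first column carry variant ids. Asymmetry up to 1e-8 is repaired by
#' averaging; the diagonal is forced to 1.
#'
#' @param path file path.
#' @return an [LdMatrix-class].
#' @export
readLdMatrix <- function(path) {
  if (!file.exists(path)) stop("I/O error: no such file: ", path)
  raw <- data.table::fread(path, sep = "\t", header = TRUE,
                           data.table = FALSE, showProgress = FALSE)
  ids <- as.character(raw[[1]])
  m <- as.matrix(raw[, -1, drop = FALSE])
  if (nrow(m) != ncol(m))
    stop("format error: LD matrix must be square (got ", nrow(m), " x ",
         ncol(m), ")")
  if (!is.numeric(m)) stop("format error: LD matrix must be numeric")
  dimnames(m) <- list(ids, ids)
  LdMatrix(m)
}

#' @rdname readLdMatrix
#' @param ld an [LdMatrix-class].
#' @export
writeLdMatrix <- function(ld, path) {
  stopifnot(is(ld, "LdMatrix"))
  m <- ld@r
  df <- data.frame(variant_id = rownames(m),
                   matrix(sprintf("%.17g", m), nrow(m),
                          dimnames = list(NULL, colnames(m))),
                   check.names = FALSE)
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}

.mrResultToList <- function(x) {
  list(method = x@method, beta = x@beta, se = x@se, ci_low = x@ciLow,
       ci_high = x@ciHigh, pvalue = x@pvalue, n_variants = x@nVariants,
       scale_factor = x@scaleFactor, odds_ratio = x@oddsRatio,
       cochran_q = x@cochranQ, cochran_q_p = x@cochranQP,
       egger_intercept = x@eggerIntercept,
       egger_intercept_se = x@eggerInterceptSE,
       egger_intercept_p = x@eggerInterceptP, multimodal = x@multimodal)
}

.mrResultFromList <- function(l) {
  num <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
  new("MrResult", method = l$method, beta = num(l$beta), se = num(l$se),
      ciLow = num(l$ci_low), ciHigh = num(l$ci_high), pvalue = num(l$pvalue),
      nVariants = as.integer(l$n_variants), scaleFactor = num(l$scale_factor),
      oddsRatio = isTRUE(l$odds_ratio), cochranQ = num(l$cochran_q),
      cochranQP = num(l$cochran_q_p), eggerIntercept = num(l$egger_intercept),
      eggerInterceptSE = num(l$egger_intercept_se),
      eggerInterceptP = num(l$egger_intercept_p),
      multimodal = isTRUE(l$multimodal))
}

.mvmrResultToList <- function(x) {
  list(method = x@method, exposures = as.list(x@exposures),
       beta = as.list(unname(x@beta)), se = as.list(unname(x@se)),
       ci_low = as.list(unname(x@ciLow)), ci_high = as.list(unname(x@ciHigh)),
       pvalue = as.list(unname(x@pvalue)),
       conditional_f = as.list(unname(x@conditionalF)),
       n_variants = x@nVariants)
}

.mvmrResultFromList <- function(l) {
  ex <- unlist(l$exposures)
  nm <- function(x) setNames(as.numeric(unlist(x)), ex)
  new("MvmrResult", method = l$method, exposures = ex, beta = nm(l$beta),
      se = nm(l$se), ciLow = nm(l$ci_low), ciHigh = nm(l$ci_high),
      pvalue = nm(l$pvalue), conditionalF = nm(l$conditional_f),
      nVariants = as.integer(l$n_variants))
}

.reportToList <- function(report) {
  d <- report@instrumentDiagnostics
  out <- list(
    provenance = report@provenance,
    instrument_diagnostics = list(
      n_instruments = d@nInstruments, r_squared = d@rSquared,
      f_statistic = d@fStatistic, inverse_f = d@inverseF,
      per_variant_f = as.list(unname(d@perVariantF))),
    harmonization = report@harmonization,
    results = lapply(report@results, .mrResultToList),
    mvmr = lapply(report@mvmr, .mvmrResultToList),
    reruns = lapply(report@reruns,
                    function(r) lapply(r, .mrResultToList)))
  if (!is.null(report@presso)) {
    p <- report@presso
    out$presso <- list(global_p = p@globalP,
                       outlier_ids = as.list(p@outlierIds),
                       raw = .mrResultToList(p@raw),
                       corrected = .mrResultToList(p@corrected),
                       n_simulations = p@nSimulations, seed = p@seed)
  }
  if (!is.null(report@mediation)) {
    m <- report@mediation
    out$mediation <- list(
      total = .mrResultToList(m@total), direct = m@direct,
      direct_se = m@directSE,
      indirect_difference = as.list(unname(m@indirectDifference)),
      indirect_product = as.list(unname(m@indirectProduct)),
      proportion_difference = as.list(unname(m@proportionDifference)),
      proportion_product = as.list(unname(m@proportionProduct)),
      ci_method = m@ciMethod, seed = m@seed)
  }
  out
}

.reportFromList <- function(l) {
  diag <- l$instrument_diagnostics
  id <- new("InstrumentDiagnostics",
            nInstruments = as.integer(diag$n_instruments),
            rSquared = as.numeric(diag$r_squared),
            fStatistic = as.numeric(diag$f_statistic),
            inverseF = as.numeric(diag$inverse_f),
            perVariantF = as.numeric(unlist(diag$per_variant_f)))
  presso <- NULL
  if (!is.null(l$presso)) {
    p <- l$presso
    presso <- new("PressoResult", globalP = as.numeric(p$global_p),
                  outlierIds = as.character(unlist(p$outlier_ids)),
                  raw = .mrResultFromList(p$raw),
                  corrected = .mrResultFromList(p$corrected),
                  nSimulations = as.integer(p$n_simulations),
                  seed = as.integer(p$seed))
  }
  mediation <- NULL
  if (!is.null(l$mediation)) {
    m <- l$mediation
    tri <- function(x) as.numeric(unlist(x))
    mediation <- new("MediationResult", total = .mrResultFromList(m$total),
                     direct = as.numeric(m$direct),
                     directSE = as.numeric(m$direct_se),
                     indirectDifference = tri(m$indirect_difference),
                     indirectProduct = tri(m$indirect_product),
                     proportionDifference = tri(m$proportion_difference),
                     proportionProduct = tri(m$proportion_product),
                     ciMethod = m$ci_method, seed = as.integer(m$seed))
  }
  new("StudyReport", provenance = l$provenance,
      instrumentDiagnostics = id,
      harmonization = l$harmonization,
      results = lapply(l$results, .mrResultFromList),
      presso = presso,
      mvmr = lapply(l$mvmr, .mvmrResultFromList),
      mediation = mediation,
      reruns = lapply(l$reruns, function(r) lapply(r, .mrResultFromList)))
}

#' Tabulate the estimates of a study report
#'
#' One row per estimate (method x analysis arm), grouped the way forest
#' plots are laid out: primary battery first, then sensitivity reruns.
#'
#' @param report a [StudyReport-class].
#' @return data.frame with method, arm, beta, se, CI, p, k.
#' @export
resultsTable <- function(report) {
  stopifnot(is(report, "StudyReport"))
  row1 <- function(arm, x)
    data.frame(arm = arm, method = x@method, beta = x@beta, se = x@se,
               ci_low = x@ciLow, ci_high = x@ciHigh, pvalue = x@pvalue,
               n_variants = x@nVariants, odds_ratio = x@oddsRatio)
  rows <- lapply(report@results, function(x) row1("primary", x))
  if (!is.null(report@presso)) {
    rows <- c(rows, list(row1("primary", report@presso@raw),
                         row1("primary", report@presso@corrected)))
  }
  for (arm in names(report@reruns))
    rows <- c(rows, lapply(report@reruns[[arm]], function(x) row1(arm, x)))
  if (!length(rows))
    return(data.frame(arm = character(), method = character(),
                      beta = numeric(), se = numeric(), ci_low = numeric(),
                      ci_high = numeric(), pvalue = numeric(),
                      n_variants = integer(), odds_ratio = logical()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write / read a study report
#'
#' `writeStudyReport` emits two files from one basename: `<path>.json`, a
#' machine-readable dump of every estimate, SE, CI, p-value, diagnostic,
#' seed and setting at full double precision, and `<path>.tsv`, a
#' human-readable estimate table grouped by analysis arm and method.
#' `readStudyReport` reconstructs the [StudyReport-class] from the JSON;
#' the round-trip is exact to within 1e-12 on all numeric fields.
#'
#' @param report a [StudyReport-class].
#' @param path basename (extensions are appended).
#' @return `writeStudyReport`: invisibly, the JSON path;
#'   `readStudyReport`: a [StudyReport-class].
#' @export
writeStudyReport <- function(report, path) {
  stopifnot(is(report, "StudyReport"))
  json_path <- paste0(path, ".json")
  dir <- dirname(json_path)
  if (!dir.exists(dir)) stop("I/O error: no such directory: ", dir)
  jsonlite::write_json(.reportToList(report), json_path, auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  tab <- resultsTable(report)
  data.table::fwrite(tab, paste0(path, ".tsv"), sep = "\t", quote = FALSE)
  invisible(json_path)
}

#' @rdname writeStudyReport
#' @export
readStudyReport <- function(path) {
  json_path <- if (grepl("\\.json$", path)) path else paste0(path, ".json")
  if (!file.exists(json_path)) stop("I/O error: no such file: ", json_path)
  l <- jsonlite::read_json(json_path, simplifyVector = FALSE)
  .reportFromList(l)
}
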