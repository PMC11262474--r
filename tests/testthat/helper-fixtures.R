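# In-code fixtures shared across the suite.

# A small well-formed variant data.frame.
makeVariants <- function(n = 3, seed = 1) {
  set.seed(seed)
  eaf <- runif(n, 0.1, 0.9)
  beta <- rnorm(n, 0, 0.05)
  se <- runif(n, 0.005, 0.02)
  data.frame(variant_id = sprintf("rs%03d", seq_len(n)),
             chromosome = "1", position = seq_len(n) * 1000L,
             effect_allele = rep(c("A", "C", "G"), length.out = n),
             other_allele = rep(c("G", "T", "T"), length.out = n),
             eaf = eaf, beta = beta, se = se,
             pvalue = 2 * pnorm(-abs(beta / se)),
             n = 10000, stringsAsFactors = FALSE)
}

makeTable <- function(n = 3, seed = 1, label = "trait") {
  GwasTable(makeVariants(n, seed), traitLabel = label)
}

# Build a HarmonizedSet directly from effect vectors (no mediator unless
# given); alleles are synthesized consistently.
makeHarmonized <- function(bx, sx, by, sy, bm = NULL, sm = NULL,
                           exposureLabel = "X", outcomeLabel = "Y",
                           mediatorLabel = if (is.null(bm)) NA_character_
                                           else "M") {
  k <- length(bx)
  v <- data.frame(variant_id = sprintf("s%04d", seq_len(k)),
                  effect_allele = "A", other_allele = "G",
                  beta_exposure = bx, se_exposure = sx,
                  beta_mediator = if (is.null(bm)) NA_real_ else bm,
                  se_mediator = if (is.null(sm)) NA_real_ else sm,
                  beta_outcome = by, se_outcome = sy,
                  stringsAsFactors = FALSE)
  new("HarmonizedSet", exposureLabel = exposureLabel,
      outcomeLabel = outcomeLabel, mediatorLabel = mediatorLabel,
      variants = v, nDroppedMismatch = 0L, nFlipped = 0L)
}

# Random harmonized instance for oracle-equivalence checks.
randomHarmonized <- function(k, seed, mediator = FALSE) {
  set.seed(seed)
  bx <- rnorm(k, 0, 0.1)
  bx[bx == 0] <- 0.05
  bm <- if (mediator) rnorm(k, 0, 0.1)
  makeHarmonized(bx = bx, sx = runif(k, 0.001, 0.01),
                 by = rnorm(k, 0, 0.05), sy = runif(k, 0.01, 0.1),
                 bm = bm, sm = if (mediator) runif(k, 0.001, 0.01))
}

mcse <- function(x) sd(x) / sqrt(length(x))
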