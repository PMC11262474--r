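.ciz <- qnorm(0.975)

.newMr <- function(method, beta, se, k, ci = NULL, pvalue = NULL,
                   q = NA_real_, qp = NA_real_, ...) {
  if (is.null(ci)) ci <- beta + c(-1, 1) * .ciz * se
  if (is.null(pvalue)) pvalue <- 2 * pnorm(-abs(beta / se))
  new("MrResult", method = method, beta = beta, se = se,
      ciLow = ci[1], ciHigh = ci[2], pvalue = pvalue,
      nVariants = as.integer(k), cochranQ = q, cochranQP = qp, ...)
}

.hcols <- function(h) {
  stopifnot(is(h, "HarmonizedSet"))
  v <- h@variants
  list(bx = v$beta_exposure, sx = v$se_exposure,
       bm = v$beta_mediator, sm = v$se_mediator,
       by = v$beta_outcome, sy = v$se_outcome, id = v$variant_id)
}

#' Wald ratio for a single variant
#'
#' The variant-outcome association divided by the variant-exposure
#' association; its standard error uses the first-order delta method
#' (`se_outcome / |beta_exposure|`), ignoring exposure-side uncertainty as
#' is standard two-sample practice when instruments are strong (F >> 10).
#' A second-order correction adding the exposure-side term is available.
#'
#' @param betaExposure,seExposure,betaOutcome,seOutcome per-variant
#'   associations (vectorized).
#' @param secondOrder if `TRUE`, se includes the exposure-side term:
#'   `sqrt(se_y^2/bx^2 + by^2 se_x^2 / bx^4)`.
#' @param variantId optional ids for error messages.
#' @return list with numeric `ratio` and `se`.
#' @export
waldRatio <- function(betaExposure, seExposure, betaOutcome, seOutcome,
                      secondOrder = FALSE, variantId = NULL) {
  zero <- betaExposure == 0
  if (any(zero)) {
    lab <- if (!is.null(variantId)) variantId[which(zero)[1]] else
      paste0("index ", which(zero)[1])
    stop("division error: beta_exposure is zero for variant ", lab)
  }
  ratio <- betaOutcome / betaExposure
  se <- if (secondOrder)
    sqrt(seOutcome^2 / betaExposure^2 +
           betaOutcome^2 * seExposure^2 / betaExposure^4)
  else seOutcome / abs(betaExposure)
  list(ratio = ratio, se = se)
}

#' Inverse-variance weighted estimate
#'
#' Pools per-variant Wald ratios by weighted least squares of the outcome
#' associations on the exposure associations through the origin, with
#' weights `1/se_outcome^2`; closed form
#' `sum(w bx by) / sum(w bx^2)`. Cochran's Q heterogeneity statistic and
#' its chi-square p-value are attached. The default multiplicative
#' random-effects model inflates the fixed-effect standard error by
#' `max(1, sqrt(Q/(k-1)))`, never deflating it below the fixed-effect
#' value. With a single variant the estimate equals that variant's Wald
#' ratio.
#'
#' @param h a [HarmonizedSet-class].
#' @param model `"multiplicative_random"` (default) or `"fixed"`.
#' @return an [MrResult-class] with method `"ivw"`.
#' @export
mrIvw <- function(h, model = c("multiplicative_random", "fixed")) {
  model <- match.arg(model)
  d <- .hcols(h)
  k <- length(d$bx)
  if (k == 0) stop("validation error: empty harmonized set")
  w <- 1 / d$sy^2
  s2 <- sum(w * d$bx^2)
  beta <- sum(w * d$bx * d$by) / s2
  se_fixed <- sqrt(1 / s2)
  if (k == 1) {
    wr <- waldRatio(d$bx, d$sx, d$by, d$sy, variantId = d$id)
    return(.newMr("wald", wr$ratio, wr$se, 1L))
  }
  q <- sum(w * (d$by - beta * d$bx)^2)
  qp <- pchisq(q, df = k - 1, lower.tail = FALSE)
  se <- if (model == "fixed") se_fixed
        else se_fixed * max(1, sqrt(q / (k - 1)))
  .newMr("ivw", beta, se, k, q = q, qp = qp)
}

#' MR-Egger regression
#'
#' Weighted least squares of outcome on exposure associations with a free
#' intercept (weights `1/se_outcome^2`), after orienting every variant so
#' its exposure association is non-negative (a sign convention required for
#' the InSIDE-based interpretation of the intercept). The slope is the
#' pleiotropy-adjusted causal estimate; a nonzero intercept indicates
#' directional horizontal pleiotropy. Standard errors use multiplicative
#' random effects (residual dispersion floored at 1) and p-values/CIs the
#' t distribution with k - 2 degrees of freedom.
#'
#' @param h a [HarmonizedSet-class] with at least 3 variants.
#' @return an [MrResult-class] with method `"egger"` and the intercept test
#'   populated (see [eggerIntercept()]).
#' @export
mrEgger <- function(h) {
  d <- .hcols(h)
  k <- length(d$bx)
  if (k < 3) stop("validation error: MR-Egger requires >= 3 variants")
  s <- ifelse(d$bx < 0, -1, 1)
  bx <- s * d$bx
  by <- s * d$by
  w <- 1 / d$sy^2
  X <- cbind(intercept = 1, slope = bx)
  xtwx <- crossprod(X, w * X)
  coef <- solve(xtwx, crossprod(X, w * by))
  resid <- by - X %*% coef
  rss <- sum(w * resid^2)
  phi <- max(1, rss / (k - 2))
  cv <- solve(xtwx) * phi
  se <- sqrt(diag(cv))
  tq <- qt(0.975, df = k - 2)
  slope <- unname(coef[2]); slope_se <- unname(se[2])
  int <- unname(coef[1]); int_se <- unname(se[1])
  .newMr("egger", slope, slope_se, k,
         ci = slope + c(-1, 1) * tq * slope_se,
         pvalue = 2 * pt(-abs(slope / slope_se), df = k - 2),
         q = rss, qp = pchisq(rss, df = k - 2, lower.tail = FALSE),
         eggerIntercept = int, eggerInterceptSE = int_se,
         eggerInterceptP = 2 * pt(-abs(int / int_se), df = k - 2))
}

# Weighted median of values x with weights w: the 50% point of the
# weight-cumulative ordered values, with linear interpolation between the
# bracketing order statistics. Equal weights reduce to the ordinary median.
.weightedMedian <- function(x, w) {
  o <- order(x)
  x <- x[o]; w <- w[o] / sum(w)
  p <- cumsum(w) - w / 2
  if (0.5 <= p[1]) return(x[1])
  if (0.5 >= p[length(p)]) return(x[length(x)])
  stats::approx(p, x, xout = 0.5, ties = "ordered")$y
}

#' Weighted-median estimator
#'
#' Weighted median of the per-variant Wald ratios with weights equal to the
#' inverse variance of each ratio (first-order delta method). Consistent
#' when variants carrying less than half the weight are invalid
#' instruments. The standard error comes from a parametric bootstrap:
#' exposure and outcome associations are resampled from normal
#' distributions centred on their estimates and the weighted median is
#' recomputed; deterministic given `seed`.
#'
#' @param h a [HarmonizedSet-class] with at least 3 variants.
#' @param nBoot number of bootstrap resamples.
#' @param seed RNG seed for the bootstrap.
#' @return an [MrResult-class] with method `"weighted_median"`.
#' @export
mrWeightedMedian <- function(h, nBoot = 1000L, seed = 1L) {
  d <- .hcols(h)
  k <- length(d$bx)
  if (k < 3)
    stop("validation error: weighted median requires >= 3 variants")
  wr <- waldRatio(d$bx, d$sx, d$by, d$sy, variantId = d$id)
  w <- 1 / wr$se^2
  est <- .weightedMedian(wr$ratio, w)
  set.seed(seed)
  boots <- vapply(seq_len(nBoot), function(i) {
    bx <- rnorm(k, d$bx, d$sx)
    by <- rnorm(k, d$by, d$sy)
    bx[bx == 0] <- .Machine$double.eps
    r <- by / bx
    s <- d$sy / abs(bx)
    .weightedMedian(r, 1 / s^2)
  }, numeric(1))
  se <- sd(boots)
  .newMr("weighted_median", est, se, k)
}

#' Contamination-mixture estimator
#'
#' Models each variant's Wald ratio as coming from either a valid component
#' `Normal(theta, se_j^2)` or an invalid component `Normal(0, se_j^2 +
#' psi^2)`; for every candidate theta on a grid each variant contributes
#' the larger of the two component log-likelihoods, and the estimate
#' maximizes the summed profile log-likelihood. The 95% confidence set is
#' `{theta : logL(max) - logL(theta) <= 1.92}` (chi-square(1)/2); when it
#' is a union of disjoint intervals the enclosing hull is reported and the
#' result is flagged multimodal. No symmetric standard error exists, so
#' `se` is `NA`.
#'
#' @param h a [HarmonizedSet-class] (single-variant sets reduce to that
#'   variant's ratio).
#' @param psi SD of invalid-instrument effects; default 1.5 times the SD of
#'   the Wald ratios.
#' @param grid optional `c(from, to)` or `c(from, to, n_points)` grid
#'   specification; default brackets the ratios with a 10,001-point grid.
#'   An estimate on the grid boundary raises a widen-grid error.
#' @return an [MrResult-class] with method `"contamination_mixture"`.
#' @export
mrConMix <- function(h, psi = NULL, grid = NULL) {
  d <- .hcols(h)
  k <- length(d$bx)
  if (k == 0) stop("validation error: empty harmonized set")
  wr <- waldRatio(d$bx, d$sx, d$by, d$sy, variantId = d$id)
  r <- wr$ratio; s <- wr$se
  if (is.null(psi)) {
    psi <- 1.5 * if (k > 1) sd(r) else abs(r[1])
    if (!is.finite(psi) || psi <= 0) psi <- 1
  }
  if (psi <= 0) stop("validation error: psi must be > 0")
  if (is.null(grid)) {
    span <- max(r + 3 * s) - min(r - 3 * s)
    grid <- c(min(r - 3 * s) - 0.05 * span, max(r + 3 * s) + 0.05 * span,
              10001)
  }
  npts <- if (length(grid) >= 3) grid[3] else 10001
  theta <- sort(unique(c(seq(grid[1], grid[2], length.out = npts), r)))
  ll_invalid <- sum(dnorm(r, 0, sqrt(s^2 + psi^2), log = TRUE))
  # profile log-likelihood over the grid, vectorized across variants
  ll <- vapply(theta, function(th) {
    sum(pmax(dnorm(r, th, s, log = TRUE),
             dnorm(r, 0, sqrt(s^2 + psi^2), log = TRUE)))
  }, numeric(1))
  imax <- which.max(ll)
  if (imax == 1L || imax == length(theta))
    stop("widen-grid error: estimate lies on the grid boundary; ",
         "supply a wider grid")
  est <- theta[imax]
  inside <- ll[imax] - ll <= qchisq(0.95, 1) / 2
  ci <- range(theta[inside])
  runs <- rle(inside)
  multimodal <- sum(runs$values) > 1
  pval <- if (k > 1) {
    # likelihood-ratio test of theta = 0 against the profile maximum
    i0 <- which.min(abs(theta))
    pchisq(2 * (ll[imax] - ll[i0]), df = 1, lower.tail = FALSE)
  } else 2 * pnorm(-abs(r[1] / s[1]))
  .newMr("contamination_mixture", est, NA_real_, k, ci = ci, pvalue = pval,
         multimodal = multimodal)
}

#' @importFrom stats qchisq
NULL

#' MR-PRESSO: pleiotropy residual sum of squares and outlier test
#'
#' Global test: the observed weighted residual sum of squares -- each
#' variant's outcome association compared with its value expected under the
#' leave-one-out inverse-variance weighted estimate -- is ranked against
#' `nSimulations` parametric datasets drawn under the no-pleiotropy model
#' (outcome associations redrawn around their leave-one-out expectations
#' with their own standard errors). Outlier test: each variant's observed
#' weighted squared residual is ranked against its simulated distribution;
#' variants with Bonferroni-corrected tail probability below `outlierAlpha`
#' are flagged. The corrected estimate is the IVW fit after removing the
#' flagged variants. Deterministic given `seed`.
#'
#' @param h a [HarmonizedSet-class] with at least 4 variants.
#' @param nSimulations number of parametric draws (>= 1).
#' @param outlierAlpha familywise level of the outlier test.
#' @param seed RNG seed.
#' @param model IVW error model for raw/corrected estimates.
#' @return a [PressoResult-class].
#' @export
mrPresso <- function(h, nSimulations = 1000L, outlierAlpha = 0.05,
                     seed = 1L, model = "multiplicative_random") {
  d <- .hcols(h)
  k <- length(d$bx)
  if (k < 4) stop("validation error: MR-PRESSO requires >= 4 variants")
  if (nSimulations < 1)
    stop("validation error: nSimulations must be >= 1")
  w <- 1 / d$sy^2
  s1 <- sum(w * d$bx * d$by)
  s2 <- sum(w * d$bx^2)
  beta_loo <- (s1 - w * d$bx * d$by) / (s2 - w * d$bx^2)
  expected <- beta_loo * d$bx
  res_obs2 <- w * (d$by - expected)^2
  rss_obs <- sum(res_obs2)

  set.seed(seed)
  # nSimulations x k matrix of outcome betas under the no-pleiotropy model
  bysim <- matrix(rnorm(nSimulations * k, mean = rep(expected,
                                                     each = nSimulations),
                        sd = rep(d$sy, each = nSimulations)),
                  nrow = nSimulations)
  s1s <- bysim %*% (w * d$bx)
  num <- sweep(bysim, 2, w * d$bx, `*`)
  beta_loo_sim <- sweep(-num, 1, s1s, `+`)
  beta_loo_sim <- sweep(beta_loo_sim, 2, s2 - w * d$bx^2, `/`)
  resid_sim <- bysim - sweep(beta_loo_sim, 2, d$bx, `*`)
  res_sim2 <- sweep(resid_sim^2, 2, w, `*`)
  rss_sim <- rowSums(res_sim2)

  global_p <- (1 + sum(rss_sim >= rss_obs)) / (nSimulations + 1)
  p_var <- (1 + colSums(sweep(res_sim2, 2, res_obs2, `>=`))) /
    (nSimulations + 1)
  flagged <- d$id[p_var < outlierAlpha / k]

  raw <- mrIvw(h, model = model)
  raw@method <- "presso_raw"
  if (length(flagged) && length(flagged) < k) {
    keep <- !(h@variants$variant_id %in% flagged)
    h2 <- h
    h2@variants <- h@variants[keep, , drop = FALSE]
    corrected <- mrIvw(h2, model = model)
  } else {
    corrected <- raw
  }
  corrected@method <- "presso_corrected"
  new("PressoResult", globalP = global_p, outlierIds = flagged,
      raw = raw, corrected = corrected,
      nSimulations = as.integer(nSimulations), seed = as.integer(seed))
}

#' Rescale an estimate and optionally express it as an odds ratio
#'
#' Multiplies the point estimate, standard error and confidence limits by
#' `scaleFactor` (e.g. 10 to report per 10-unit increase in the exposure).
#' With `asOddsRatio = TRUE` the scaled point estimate and confidence
#' limits are then exponentiated (appropriate for binary outcomes on the
#' log-odds scale); the standard error stays on the log scale.
#'
#' @param r an [MrResult-class].
#' @param scaleFactor nonzero exposure-units-per-reported-unit factor.
#' @param asOddsRatio exponentiate to an odds-ratio scale.
#' @return the transformed [MrResult-class].
#' @export
transformEstimate <- function(r, scaleFactor = 10, asOddsRatio = FALSE) {
  stopifnot(is(r, "MrResult"))
  if (scaleFactor == 0)
    stop("validation error: scaleFactor must be nonzero")
  if (r@oddsRatio)
    stop("validation error: estimate is already on the odds-ratio scale")
  out <- r
  out@beta <- r@beta * scaleFactor
  out@se <- r@se * abs(scaleFactor)
  ci <- sort(c(r@ciLow * scaleFactor, r@ciHigh * scaleFactor))
  out@ciLow <- ci[1]
  out@ciHigh <- ci[2]
  out@scaleFactor <- r@scaleFactor * scaleFactor
  if (asOddsRatio) {
    out@beta <- exp(out@beta)
    out@ciLow <- exp(out@ciLow)
    out@ciHigh <- exp(out@ciHigh)
    out@oddsRatio <- TRUE
  }
  validObject(out)
  out
}
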