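.mvmrDesign <- function(h) {
  d <- .hcols(h)
  if (all(is.na(d$bm)))
    stop("validation error: harmonized set carries no mediator column")
  d
}

#' Multivariable inverse-variance weighted MR
#'
#' Weighted least squares of the variant-outcome associations jointly on
#' the variant-exposure and variant-mediator associations, intercept
#' constrained at the origin, weights `1/se_outcome^2`. Each coefficient is
#' that exposure's effect on the outcome holding the other constant: the
#' exposure coefficient is its direct effect. Standard errors use
#' multiplicative random effects (residual dispersion floored at 1).
#'
#' A mediator column that is identically zero is treated as a degenerate
#' design: the model is refitted on the exposure alone (so the exposure
#' coefficient equals the univariable fixed-effect IVW exactly) and the
#' mediator coefficient is reported as `NA`. Any other rank deficiency
#' (collinear columns) is an estimation error.
#'
#' @param h a [HarmonizedSet-class] with mediator columns and >= 3
#'   variants.
#' @param computeConditionalF attach Sanderson-Windmeijer-style conditional
#'   F statistics (see [conditionalF()]).
#' @return an [MvmrResult-class] with method `"mvmr_ivw"`.
#' @export
mvmrIvw <- function(h, computeConditionalF = TRUE) {
  d <- .mvmrDesign(h)
  k <- length(d$bx)
  if (k < 3) stop("validation error: MVMR requires >= 3 variants")
  labels <- c(h@exposureLabel, h@mediatorLabel)
  w <- 1 / d$sy^2
  zero_med <- all(d$bm == 0)
  if (zero_med) {
    # degenerate second column: reduce to the univariable IVW closed form
    s2 <- sum(w * d$bx^2)
    coef <- sum(w * d$bx * d$by) / s2
    phi <- max(1, sum(w * (d$by - coef * d$bx)^2) / (k - 1))
    coef <- c(coef, NA_real_)
    se <- c(sqrt(phi / s2), NA_real_)
  } else {
    X <- cbind(d$bx, d$bm)
    xtwx <- crossprod(X, w * X)
    if (rcond(xtwx) < 1e-12)
      stop("estimation error: rank-deficient design (collinear exposure ",
           "and mediator columns)")
    coef <- drop(solve(xtwx, crossprod(X, w * d$by)))
    resid <- d$by - drop(X %*% coef)
    phi <- max(1, sum(w * resid^2) / (k - 2))
    se <- sqrt(diag(solve(xtwx)) * phi)
  }
  cf <- if (computeConditionalF) conditionalF(h) else
    setNames(c(NA_real_, NA_real_), labels)
  names(coef) <- names(se) <- labels
  new("MvmrResult", method = "mvmr_ivw", exposures = labels,
      beta = coef, se = se,
      ciLow = coef - .ciz * se, ciHigh = coef + .ciz * se,
      pvalue = 2 * pnorm(-abs(coef / se)),
      conditionalF = setNames(as.numeric(cf), labels),
      nVariants = as.integer(k))
}

#' Conditional instrument-strength F statistics
#'
#' For each exposure in the two-exposure design, the strength of its
#' instruments conditional on the other exposure: that exposure's variant
#' associations are regressed through the origin on the other exposure's
#' associations (weights `1/se_outcome^2`) and the statistic is the mean
#' scaled squared residual, `(1/k) * sum(resid_j^2 / se_j^2)` with `se_j`
#' the exposure's own per-variant standard error. When the other exposure's
#' associations are identically zero this reduces to the exposure's
#' marginal mean F; when the two association vectors are collinear it tends
#' to zero. Values below 10 indicate conditionally weak instruments.
#'
#' @param h a [HarmonizedSet-class] with mediator columns and >= 3
#'   variants.
#' @return named numeric: conditional F for the exposure and the mediator.
#' @export
conditionalF <- function(h) {
  d <- .mvmrDesign(h)
  k <- length(d$bx)
  if (k < 3) stop("validation error: conditional F requires >= 3 variants")
  w <- 1 / d$sy^2
  condOne <- function(a, sa, b) {
    denom <- sum(w * b^2)
    resid <- if (denom == 0) a else a - (sum(w * a * b) / denom) * b
    mean(resid^2 / sa^2)
  }
  setNames(c(condOne(d$bx, d$sx, d$bm), condOne(d$bm, d$sm, d$bx)),
           c(h@exposureLabel, h@mediatorLabel))
}

#' Q-minimization multivariable MR (Qhet)
#'
#' Estimates the two direct effects by minimizing the heterogeneity
#' statistic
#' \deqn{Q(\theta) = \sum_j \frac{(b_{Y,j} - \theta_1 b_{X,j} - \theta_2
#'   b_{M,j})^2}{se_{Y,j}^2 + \theta_1^2 se_{X,j}^2 + \theta_2^2
#'   se_{M,j}^2}}
#' whose denominator propagates the exposure- and mediator-side sampling
#' variances, making the estimator robust to conditionally weak
#' instruments. Minimization is by Nelder-Mead started at the MVMR-IVW
#' coefficients (ordinary least squares when that fit is degenerate);
#' confidence intervals come from a parametric bootstrap (exposure,
#' mediator and outcome associations redrawn around their estimates,
#' deterministic given `seed`); `nBoot = 0` skips the bootstrap and
#' reports `NA` intervals.
#'
#' @param h a [HarmonizedSet-class] with mediator columns and >= 3
#'   variants.
#' @param nBoot bootstrap draws for the CIs (default 500).
#' @param seed RNG seed.
#' @param reltol optimizer convergence tolerance.
#' @return an [MvmrResult-class] with method `"qhet"`.
#' @export
qhetMvmr <- function(h, nBoot = 500L, seed = 1L, reltol = 1e-12) {
  d <- .mvmrDesign(h)
  k <- length(d$bx)
  if (k < 3) stop("validation error: Qhet MVMR requires >= 3 variants")
  labels <- c(h@exposureLabel, h@mediatorLabel)
  qfun <- function(th, bx, bm, by) {
    sum((by - th[1] * bx - th[2] * bm)^2 /
          (d$sy^2 + th[1]^2 * d$sx^2 + th[2]^2 * d$sm^2))
  }
  fitOne <- function(bx, bm, by) {
    start <- tryCatch(
      drop(solve(crossprod(cbind(bx, bm), (1 / d$sy^2) * cbind(bx, bm)),
                 crossprod(cbind(bx, bm), (1 / d$sy^2) * by))),
      error = function(e) c(0, 0))
    opt <- stats::optim(start, qfun, bx = bx, bm = bm, by = by,
                        method = "Nelder-Mead",
                        control = list(reltol = reltol, maxit = 5000))
    if (opt$convergence != 0)
      stop("estimation error: Qhet optimizer failed to converge (code ",
           opt$convergence, ")")
    opt$par
  }
  est <- fitOne(d$bx, d$bm, d$by)
  if (nBoot > 0) {
    set.seed(seed)
    boots <- t(vapply(seq_len(nBoot), function(i) {
      fitOne(rnorm(k, d$bx, d$sx), rnorm(k, d$bm, d$sm),
             rnorm(k, d$by, d$sy))
    }, numeric(2)))
    se <- apply(boots, 2, sd)
    ci <- apply(boots, 2, quantile, probs = c(0.025, 0.975))
    ci_low <- pmin(ci[1, ], est)
    ci_high <- pmax(ci[2, ], est)
    pv <- 2 * pnorm(-abs(est / se))
  } else {
    se <- ci_low <- ci_high <- pv <- c(NA_real_, NA_real_)
  }
  names(est) <- names(se) <- labels
  new("MvmrResult", method = "qhet", exposures = labels, beta = est,
      se = setNames(se, labels),
      ciLow = setNames(ci_low, labels), ciHigh = setNames(ci_high, labels),
      pvalue = setNames(pv, labels),
      conditionalF = setNames(as.numeric(conditionalF(h)), labels),
      nVariants = as.integer(k))
}

#' Decompose a total effect into direct and indirect components
#'
#' Mediation decomposition combining the univariable (total) estimate with
#' the multivariable (direct) estimates. Two indirect-effect estimators are
#' reported: the difference method `total - direct` and the network
#' (two-step) product method `theta_XM * theta_MY`, where `theta_XM` is the
#' univariable exposure-to-mediator estimate and `theta_MY` the mediator's
#' direct effect from the multivariable fit. The proportion mediated is
#' each indirect effect divided by the total effect; negative proportions
#' are legitimate when the direct and indirect paths oppose.
#'
#' Delta-method intervals treat the component estimates as independent (a
#' conservative convention in the two-sample setting); the default
#' parametric bootstrap resamples the components from normal distributions
#' around their estimates and reports percentile intervals, which may be
#' asymmetric. Deterministic given `seed`.
#'
#' @param total the univariable [MrResult-class] for exposure -> outcome.
#' @param mvmr the [MvmrResult-class] of the joint fit (exposure first,
#'   mediator second).
#' @param twoStepThetaXM the univariable [MrResult-class] for
#'   exposure -> mediator.
#' @param ciMethod `"bootstrap"` (default) or `"delta"`.
#' @param nBoot bootstrap draws.
#' @param seed RNG seed.
#' @return a [MediationResult-class].
#' @export
decomposeMediation <- function(total, mvmr, twoStepThetaXM,
                               ciMethod = c("bootstrap", "delta"),
                               nBoot = 5000L, seed = 1L) {
  stopifnot(is(total, "MrResult"), is(mvmr, "MvmrResult"),
            is(twoStepThetaXM, "MrResult"))
  ciMethod <- match.arg(ciMethod)
  direct <- unname(mvmr@beta[1])
  direct_se <- unname(mvmr@se[1])
  theta_my <- unname(mvmr@beta[2])
  theta_my_se <- unname(mvmr@se[2])
  theta_xm <- twoStepThetaXM@beta
  theta_xm_se <- twoStepThetaXM@se
  tot <- total@beta
  tot_se <- total@se
  if (is.na(theta_my))
    stop("estimation error: mediator coefficient unavailable in the MVMR fit")

  ind_diff <- tot - direct
  ind_prod <- theta_xm * theta_my
  if (tot == 0)
    stop("undefined-proportion error: total effect is zero; indirect ",
         "effects are ", signif(ind_diff, 4), " (difference) and ",
         signif(ind_prod, 4), " (product)")
  pm_diff <- ind_diff / tot
  pm_prod <- ind_prod / tot

  if (ciMethod == "delta") {
    # independence-based variance propagation
    v_diff <- tot_se^2 + direct_se^2
    v_prod <- theta_xm^2 * theta_my_se^2 + theta_my^2 * theta_xm_se^2
    ci_diff <- ind_diff + c(-1, 1) * .ciz * sqrt(v_diff)
    ci_prod <- ind_prod + c(-1, 1) * .ciz * sqrt(v_prod)
    # proportion mediated: pm_diff = 1 - direct/total
    g_diff <- sqrt((direct_se / tot)^2 + (direct * tot_se / tot^2)^2)
    g_prod <- sqrt(v_prod / tot^2 + (ind_prod * tot_se / tot^2)^2)
    ci_pm_diff <- pm_diff + c(-1, 1) * .ciz * g_diff
    ci_pm_prod <- pm_prod + c(-1, 1) * .ciz * g_prod
    seed_used <- NA_integer_
  } else {
    set.seed(seed)
    tot_b <- rnorm(nBoot, tot, tot_se)
    dir_b <- rnorm(nBoot, direct, direct_se)
    xm_b <- rnorm(nBoot, theta_xm, theta_xm_se)
    my_b <- rnorm(nBoot, theta_my, theta_my_se)
    idiff_b <- tot_b - dir_b
    iprod_b <- xm_b * my_b
    qs <- function(x) unname(quantile(x, c(0.025, 0.975)))
    ci_diff <- qs(idiff_b)
    ci_prod <- qs(iprod_b)
    ci_pm_diff <- qs(idiff_b / tot_b)
    ci_pm_prod <- qs(iprod_b / tot_b)
    seed_used <- as.integer(seed)
  }
  new("MediationResult", total = total, direct = direct,
      directSE = direct_se,
      indirectDifference = c(ind_diff, ci_diff),
      indirectProduct = c(ind_prod, ci_prod),
      proportionDifference = c(pm_diff, ci_pm_diff),
      proportionProduct = c(pm_prod, ci_pm_prod),
      ciMethod = ciMethod, seed = seed_used)
}
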