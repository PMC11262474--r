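---
title: "Methods: two-sample MR with multivariable mediation analysis"
author: "mrmediate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR with multivariable mediation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmediate)
```

# The problem

Two-sample Mendelian randomization (MR) estimates the causal effect of an
exposure (e.g. systolic blood pressure) on an outcome (e.g. intraocular
pressure, retinal-layer thickness, or glaucoma liability) using only GWAS
summary statistics from separate samples. Genetic variants robustly
associated with the exposure serve as randomized instruments: because
alleles are allocated at conception, variant-outcome associations are
protected from the environmental confounding and measurement error that
undermine observational estimates. A mediation extension asks how much of
the exposure's total effect is routed through an intermediate trait (e.g.
whether blood pressure damages retinal ganglion cells via raised
intraocular pressure or independently of it).

`mrmediate` implements the full design as a reusable, tested pipeline:
instrument selection, allele harmonization, the inverse-variance weighted
(IVW) estimator with a pleiotropy-robust sensitivity battery, and
multivariable MR (MVMR) mediation analysis — plus a synthetic
summary-statistics generator with known structural truth, so that every
stage can be verified by parameter recovery rather than trusted on faith.

# The structural model behind the generator

The generator works directly at the summary level; no individual-level
genotypes are simulated, because every downstream computation consumes
only summary statistics. For variant $j$ with effect-allele frequency
$f_j$:

* $\gamma_j$ — true variant-exposure effect, nonzero with probability
  `causalFraction`, drawn $N(0, \sigma_\gamma^2)$;
* $\delta_j$ — mediator-specific effect, nonzero with probability
  `mediatorSpecificFraction`, drawn $N(0, \sigma_\delta^2)$;
* $\alpha_j$ — horizontal pleiotropy on the outcome (`none`, `balanced`
  = mean zero, or `directional` = nonzero mean).

True effects follow the linear structural equations

$$ b_{M,j} = \theta_{XM}\,\gamma_j + \delta_j, \qquad
   b_{Y,j} = \theta_{direct}\,\gamma_j + \theta_{MY}\, b_{M,j} + \alpha_j $$

so that $\theta_{total} = \theta_{direct} + \theta_{XM}\theta_{MY}$ holds
exactly and the true proportion mediated is
$\theta_{XM}\theta_{MY}/\theta_{total}$. Observed estimates add
$N(0, se_j^2)$ noise with $se_j = 1/\sqrt{2 f_j (1-f_j) N}$, the standard
error of a variance-standardized GWAS of size $N$; doubling $N$ shrinks
every standard error by exactly $1/\sqrt 2$.

The mediator-specific effects $\delta_j$ deserve a note. If the mediator's
instrument effects were purely $\theta_{XM}\gamma_j$, the exposure and
mediator columns of the MVMR design would be exactly collinear and the
joint model unidentified; real mediators (such as intraocular pressure)
have genetic determinants of their own. `mediatorSpecificFraction` and
`deltaSd` control that independent variation; setting `deltaSd = 0`
recovers the degenerate fully-proportional case, which `mvmrIvw()` treats
as an error (or, when the mediator column is exactly zero, as a reduction
to univariable IVW).

Default sample sizes (757,601 exposure; 139,555 mediator; 33,129 outcome)
mirror the largest published blood-pressure and intraocular-pressure GWAS
meta-analyses and an OCT outcome GWAS, giving realistic standard-error
magnitudes; `gammaSd = 0.02` puts typical instruments at genome-wide
significance at the exposure sample size. LD is block-diagonal
compound-symmetric — the simplest structure that exercises clumping. What
the generator deliberately does **not** emulate: population
stratification, sample overlap between GWAS, trans-ancestry structure,
LD-correlated effect estimates, or liability-scale conversion for binary
traits (binary outcomes are generated and analysed on the log-odds
scale). Passing tests therefore demonstrate correctness of the estimators
under the stated model, not robustness to those additional features of
real data.

Two bias mechanisms can be switched on after simulation:

* **Winner's curse** — `applyWinnersCurse()` replaces each estimate by a
  draw from a normal centred on the true effect but truncated to the
  two-sided rejection region $|\hat\beta| > z\,se$ of a discovery
  threshold: the distribution of an estimate *conditional on the variant
  having been discovered*. Null or marginal variants are strongly
  inflated; variants far from the boundary ($|\beta|/se \gg z$) are
  essentially untouched. A threshold of 1 applies no selection and
  returns the table unchanged.
* **Collider distortion** — `applyCovariableAdjustment()` shifts each
  exposure estimate by $-s \cdot c_j$, the first-order distortion a GWAS
  adjusted for a heritable covariable (e.g. BMI in a blood-pressure GWAS)
  induces; the direction of the resulting MR bias depends on how the
  covariable effects align with the outcome pathway and can point either
  toward or away from the null.

# Instrument selection

`selectByPvalue()` retains variants strictly below a p-value threshold
(default $5\times10^{-8}$; the winner's-curse-robust rerun uses
$10^{-11}$). `ldClump()` then applies the greedy rule: repeatedly take the
remaining variant with the smallest p-value as an index and discard
everything in LD with it at $r^2 \ge$ the threshold (default 0.01).
P-value ties are broken by $|\beta|/se$ descending and then variant id,
so the output is invariant to input row order. Clumping runs against a
user-supplied or simulated LD matrix rather than a genotype reference
panel; that keeps the pipeline self-contained and testable.

`instrumentStrength()` reports per-variant $F_j = (\beta_j/se_j)^2$,
their mean $F$ (values $>10$ indicate low weak-instrument risk), $1/F$
(the approximate relative magnitude of weak-instrument bias), and $R^2$.
Because the source analyses report $R^2$ without stating a formula, two
conventions are offered: the default sums the per-variant approximation
$F_j/(F_j + n_j - 2)$, which needs no allele frequencies; a flag switches
to $\sum_j 2 f_j (1-f_j) \beta_j^2$, which assumes a standardized trait.

# Harmonization

`harmonize()` intersects tables on variant id and aligns the outcome's
effects to the exposure's effect allele: swapped allele pairs flip the
outcome beta sign (and reflect eaf); non-palindromic pairs may also be
reconciled through a strand complement, which makes all downstream
estimates invariant to strand-flipped outcome files. Palindromic (A/T,
C/G) variants are retained and aligned by their nominal labels — no
strand or frequency inference and no exclusions. Irreconcilable pairs are
dropped and counted. For the joint design, `unionInstruments()` takes the
union of the independently selected-and-clumped exposure and mediator
instruments and re-clumps it jointly at the same $r^2$ threshold (each
variant's priority is its smaller p-value); the union convention is used
because both exposures need relevance in the joint model, and it is
recorded as a convention since source analyses rarely state their MVMR
instrument construction.

# Univariable estimators

All estimators consume a `HarmonizedSet` and ignore exposure-side
uncertainty in the first instance (the standard two-sample practice at
$F \gg 10$); a second-order Wald-ratio standard error is available behind
a flag.

* **Wald ratio** — $\hat\theta_j = b_{Y,j}/b_{X,j}$, se
  $= se_{Y,j}/|b_{X,j}|$.
* **IVW** — weighted regression of $b_Y$ on $b_X$ through the origin,
  weights $1/se_Y^2$; closed form
  $\sum w b_X b_Y / \sum w b_X^2$. Default multiplicative random effects
  inflate the fixed-effect se by $\max(1, \sqrt{Q/(k-1)})$ (never
  deflating it), with Cochran's $Q$ attached; a fixed-effect flag exists.
  The choice of a multiplicative-random-effects default follows the
  reference implementations of the field.
* **MR-Egger** — the same regression with a free intercept, after
  orienting all variants to non-negative exposure effects (required for
  the InSIDE-based reading of the intercept). The intercept and its
  $t_{k-2}$ p-value form the directional-pleiotropy test.
* **Weighted median** — the 50% point of the weight-cumulative ordered
  Wald ratios with linear interpolation, weights $1/se(\hat\theta_j)^2$;
  consistent while invalid variants carry under half the weight. Standard
  error by parametric bootstrap (betas resampled around their estimates),
  deterministic given its seed.
* **Contamination mixture** — each ratio comes from a valid component
  $N(\theta, se_j^2)$ or an invalid component $N(0, se_j^2 + \psi^2)$;
  each variant contributes the larger of the two log-likelihoods and the
  profile is maximized over a grid. Default $\psi$ = 1.5 × SD of the
  ratios and a 10,001-point grid bracketing the ratios, conventions of
  the method's published description; the 95% set is
  $\{\theta: \Delta \log L \le 1.92\}$, reported as its enclosing hull
  with a multimodality flag, and an estimate on the grid boundary raises
  a widen-grid error rather than being silently truncated.
* **MR-PRESSO** — the observed weighted residual sum of squares around
  leave-one-out IVW expectations is ranked against parametric draws under
  the no-pleiotropy model (default 1000 simulations); per-variant
  residuals give Bonferroni-corrected outlier flags (level 0.05) and the
  corrected estimate is IVW after their removal. The simulation perturbs
  the outcome side only (exposure effects held fixed), immaterial at
  strong instruments; the distortion test is not implemented.

`transformEstimate()` rescales estimates to reporting units (default
per-10-unit, e.g. per 10 mmHg) and exponentiates point and interval to an
odds ratio for binary outcomes, keeping the se on the log scale.

# Multivariable MR and mediation

`mvmrIvw()` regresses $b_Y$ jointly on $(b_X, b_M)$ with no intercept and
weights $1/se_Y^2$. Although mediation methodology is sometimes described
as weighting "by the inverse of the standard error", inverse-*variance*
weighting is used here: it is the universal MVMR-IVW convention and is
the unique choice under which the model with a zero mediator column
reduces exactly to univariable IVW. The exposure coefficient is the
direct effect (the exposure's effect holding the mediator constant).
Conditional instrument strength follows a Sanderson–Windmeijer-style
construction: each exposure's variant effects are regressed through the
origin on the other exposure's (weights $1/se_Y^2$) and the statistic is
the mean scaled squared residual
$(1/k)\sum_j r_j^2/se_j^2$, which reduces to the marginal mean $F$ when
there is nothing to condition on and tends to zero under collinearity.

`qhetMvmr()` minimizes
$Q(\theta) = \sum_j (b_{Y,j} - \theta_1 b_{X,j} - \theta_2 b_{M,j})^2 /
(se_{Y,j}^2 + \theta_1^2 se_{X,j}^2 + \theta_2^2 se_{M,j}^2)$,
whose denominator propagates the exposure- and mediator-side sampling
variances; this is the sensitivity analysis robust to conditionally weak
instruments. Minimization is Nelder-Mead from the MVMR-IVW start with a
$10^{-12}$ relative tolerance. Confidence intervals use a parametric
bootstrap (default 500 draws) rather than inverting $Q$ against a
chi-square threshold, because $Q$-inversion can produce empty or disjoint
sets exactly in the weak-instrument settings the method targets.

`decomposeMediation()` reports the indirect effect two ways: the
**difference** method, total − direct, and the **network (two-step)
product** method, $\theta_{XM} \times \theta_{MY}$, where $\theta_{XM}$
is the univariable exposure-to-mediator estimate and $\theta_{MY}$ the
mediator's conditional (direct) effect from the MVMR fit — using the
conditional rather than a marginal mediator-outcome estimate is recorded
as a convention. The proportion mediated is each indirect effect over the
total; negative values are legitimate whenever the direct and indirect
paths oppose. Delta-method intervals treat components as independent
(conservative in the two-sample setting); the default parametric
bootstrap (5000 draws) yields the asymmetric intervals typical of
reported proportions.

# Pipeline, determinism and degenerate inputs

`runStudy()` chains selection → clumping → harmonization → the
univariable battery → (optionally) union instruments → MVMR +
conditional F + Qhet → decomposition, then reruns IVW at the stricter
winner's-curse threshold and, when an unadjusted exposure table is
supplied, the collider-bias rerun; `compareReruns()` tabulates each
method's pair of estimates in units of combined standard error with
sign/CI-overlap flags. Every stochastic component takes an explicit seed
recorded in the report, and identical configurations produce
byte-identical machine-readable reports. Stage failures carry the stage
name.

Numerical and degenerate-input choices worth knowing:

* IVW with one variant returns the Wald ratio (labelled `wald`).
* A mediator column identically zero is a *reduction*, not an error;
  genuinely collinear columns are an estimation error
  (reciprocal condition number below $10^{-12}$).
* P-values recomputed from beta/se are floored at the smallest positive
  double; stored p-values disagreeing with beta/se by more than 10%
  relative raise a warning, never a rejection.
* LD matrices are symmetrized by averaging when asymmetric within
  $10^{-8}$ and their diagonal is forced to 1; larger asymmetry or
  $|r| > 1$ is an error.
* Missing eaf is permitted and only disables frequency-based
  diagnostics; coordinates are 1-based and carried for interoperability
  only.

# Problem sizes used in the test suite

The suite verifies the estimators against independent weighted
least-squares oracles on 50 random instances, exact reductions and
noiseless-recovery identities, and then stochastic properties at the
following scales, chosen to give stable Monte-Carlo bands on a single
CPU: parameter recovery and coverage over 500 replicates of 150-variant
triplets at the default (paper-scale) sample sizes; Egger-intercept and
MR-PRESSO calibration over 500 replicates (200 and 50 variants); outlier
detection over 200 replicates; mediation recovery over 300 replicates
per scenario; weak-instrument comparisons over 300 replicates; and
exhaustive clumping verification on all random instances of up to 12
variants. The acceptance script runs two synthetic studies end to end
with generating effects of 0.017 per exposure unit
(exposure → pressure-analogue) and −0.02 per unit with zero mediation
(exposure → thin-tissue outcome), sized so both are well determined at
the emulated sample sizes.

# Known limitations

Single mediator only; no MVMR-Egger, MR-RAPS, mode-based or Steiger
methods; no non-linear MR; no distance-window clumping, proxy search or
reference-panel LD; no liability-scale conversion for binary outcomes.
The generator's independence assumptions (no LD between effect
estimates, no sample overlap) mean calibration results should be read as
model-based verification, not as guarantees for arbitrary real datasets.
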