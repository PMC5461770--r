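---
title: "Modeling trajectory divergence with hierarchical piecewise regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling trajectory divergence with hierarchical piecewise regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bhpr)
```

## The scientific problem

Many risk factors develop through distinct phases: body-mass index, for
example, rises steeply through childhood and adolescence and then settles
onto a much flatter adult rate. When a cohort is split by a distal outcome
(say, adult type 2 diabetes), the substantive question is often not *whether*
the groups end up different but *when* their trajectories began to diverge —
a quantity that pinpoints candidate windows for early intervention.

The traditional answer fits a mixed model with age as an unordered
categorical factor and walks the per-age group contrasts (LS-means) until
one is significant. That read-out conflates divergence with statistical
power: a smaller group reaches significance later, so the estimated
divergence age drifts upward as the sample shrinks, and nothing ties the
per-age answers to a coherent growth curve. `bhpr` instead models each
subject's full trajectory and treats the age at divergence as a model
parameter with a posterior distribution.

## Model

The level-1 mean is a continuous broken stick with subject-specific
parameters:

$$\mu_{ij} = b_{0i} + b_{1i}\,(age_{ij} - a_{ref}) + b_{2i}\,(age_{ij} - CP_i)_+ \;+\; \textstyle\sum_k \beta_{tvc,k}\,TVC_{ijk},
\qquad y_{ij} \sim N(\mu_{ij}, \sigma^2_e).$$

`b0` is the expected response at the reference age `a_ref` (so its
interpretation follows the centering), `b1` the pre-change-point slope in
units per year, `b2` the *change* in slope after the change point (the adult
slope is `b1 + b2`), and `CP` the change point in years on the raw age
scale. We use the continuous form deliberately: a specification that
switches the `b1` term off after the change point would jump at `CP`, which
is both biologically implausible for growth outcomes and statistically
fragile (the likelihood rewards placing the jump between adjacent
observations). Continuity also makes the two slopes directly comparable —
e.g. a childhood rate of 0.67 kg/m²/yr with `b2 = -0.49` means an adult
rate of 0.18 kg/m²/yr.

At level 2 each trajectory parameter is a population value plus an optional
binary-group shift, optional time-invariant covariate (TIC) terms, and a
random effect. A grouping factor with `k > 2` levels (e.g. birth cohorts in
an accelerated longitudinal design) enters through `k - 1` dummy TICs
created by `make_cohort_dummies()`, each shifting the conditional mean of
whichever trajectory parameters it is attached to.

**Divergence mechanisms.** Holding the intercept and childhood slope common
and freeing different subsets of `{beta_2grp, beta_CPgrp}` yields the three
divergence types — different adult slopes (Type I), different change-point
timing (Type II), or both (Type III). `divergence_type()` names nine
candidate models `A`–`H` spanning these and the intercept/childhood-slope
variants; `fit_divergence_suite()` fits a chosen subset and ranks them.
Under Type II, the reference group's `CP` is the age at divergence.

**Covariance structures.** The random effects are multivariate normal with
either a full unstructured covariance, mutual independence, or a
`block_b1b2` structure in which only the two slope random effects are
correlated. The block form is the pragmatic middle ground: the two slopes
of a subject are empirically correlated, while a fully unstructured 4×4
covariance is often over-parameterized for cohort data and can stall
convergence. The default in `bhpr_model()` is `independent` with a random
intercept only; richer structures are opt-in.

## Priors and their defaults

* Fixed effects (including all group shifts and TVC coefficients):
  independent normals, mean 0, variance $10^4$ — effectively flat on the
  scales of growth data. All normal priors in this package are stated in
  mean/**variance** form; a prior "variance" of 0.001 would be so
  informative as to pin the parameter, which is why we treat every default
  as vague ($10^4$) and let `prior_set()` override per parameter.
* Population change point: normal with variance $10^4$; its **mean** is set
  at model build from the profile log-likelihood estimate
  (`profile_loglik_cp()`), which fits the two-slope fixed-effects model by
  least squares on a 0.5-yr grid spanning `[age_min + 2, age_max - 2]` and
  takes the maximizing grid value (smallest on ties, for reproducibility).
  Anchoring the prior mean this way costs nothing in posterior terms (the
  prior is flat) but starts the random-walk updates in the right region and
  shortens burn-in considerably.
* Variance components: Inverse-Gamma(0.001, 0.001) per independent
  component; inverse-Wishart with identity scale and `dim + 1` degrees of
  freedom for correlated blocks.
* Modelled time-varying covariates: normal likelihood with a vague normal
  prior on the mean and Gamma(0.001, 0.001) on the precision.

## Sampler

`bhpr_fit()` runs Metropolis-within-Gibbs:

* all linear fixed effects jointly by a conjugate normal draw;
* random effects on `b0`, `b1`, `b2` by conjugate normal draws — vectorized
  over subjects for independent components, per-subject multivariate draws
  (conditioned on the other components through the current covariance) for
  correlated blocks;
* $\sigma^2_e$ and independent random-effect variances by Inverse-Gamma,
  correlated blocks by inverse-Wishart;
* every change-point parameter (population `CP`, group shift, CP TIC
  coefficients, and subject-level `vCP_i`) by scalar random-walk
  Metropolis with Robbins–Monro adaptation towards a 0.44 acceptance rate,
  frozen at the end of burn-in so the post-burn-in chain is a fixed Markov
  kernel;
* missing entries of modelled TVCs redrawn each sweep from their full
  conditional (prior model × response likelihood). The TVC mean/precision
  hyperparameters are updated from the *observed* entries only, so the
  imputation model is informed by the observed part of the data and never
  feeds back its own imputations.

**Change-point support.** Subject-level change points are constrained to
the declared observation window: population-CP proposals are reflected at
the window boundary and subject-level proposals outside it are rejected.
Without this, subjects observed on only one side of a candidate change
point let `CP_i` wander unboundedly, destroying identifiability.

**Initialization.** Two-stage least squares: the change point from the
profile log-likelihood, slopes and intercept from the corresponding linear
fit, random effects at zero, variances at method-of-moments estimates. Each
chain perturbs these by a small jitter (`jitter = 0.1` by default) so the
Gelman–Rubin diagnostic starts from genuinely dispersed points.

**Diagnostics.** `gelman_rubin()` computes the split-chain potential scale
reduction factor and flags parameters above 1.1. Values that the classical
formula would place fractionally below 1 (possible when the between-chain
variance is essentially zero, because of the $(n-1)/n$ factor) are floored
at 1. The per-draw deviance and signed residual sum are recorded at every
kept draw.

## Model comparison and adequacy

`compute_dic()` uses the conditional (level-1) focus: the deviance treats
the random effects as parameters, and the plug-in deviance is evaluated at
the posterior means of everything, including random effects and imputed
TVC values; then $p_D = \bar D - \hat D$ and $DIC = \bar D + p_D$. The
focus matters — a marginalized focus would integrate the random effects out
and give different $p_D$ — and the conditional choice matches the deviance
the sampler actually records. This is a documented convention of the
package, not the only defensible one.

`posterior_predictive_pvalue()` uses the signed sum of residuals as its
default discrepancy, computed identically for observed and replicated data
at each kept draw (replicates are simulated conditional on that draw's
random effects); a sum-of-squares alternative is available via
`statistic = "sumsq"`. Values near 0.5 indicate adequacy. The signed sum is
a deliberately weak omnibus statistic: it detects systematic location
misfit but not, say, variance misspecification — which is why it
accompanies, rather than replaces, DIC ranking.

`fit_divergence_suite()` selects the converged model with the lowest DIC,
preferring models whose PP p-value lies in [0.2, 0.8]; exact ties go to the
model with fewer free group shifts (parsimony).

## The LS-means baseline

`fit_categorical_mixed()` fits `response ~ factor(age) * group +
(1 | subject)` with lme4 and extracts per-age LS-means and group contrasts
with emmeans (asymptotic mode; the studentized-range adjustment then uses
the residual degrees of freedom `n - p`). The multiplicity family is the
set of per-age group contrasts — the comparisons actually read out — and
the Tukey adjustment uses the studentized range with the number of cell
means spanned by that family (twice the number of contrasts); with a single
contrast it reduces exactly to the unadjusted two-sided t-test.

Two divergence-age read-outs are provided. The *earliest significant age*
takes the literal first age level with adjusted p < α, even if isolated.
The *midway* rule places a cut between consecutive age levels minimizing
misclassified levels (significant before the cut plus non-significant
after), ties resolved to the earliest cut, and returns the pair's midpoint;
when every level is significant it returns the first level, and when none
is it returns `NA`. Non-estimable contrasts (empty cells in unbalanced
designs) are excluded from the family and never count as significant. The
midway wording admits several tie conventions; the one above is this
package's, stated rather than inherited.

For simulated data the exact visit ages serve as factor levels; ragged
real data require explicit `age_breaks`.

## The simulator

`sim_scenario()`/`simulate_dataset()` generate accelerated longitudinal
designs: baseline ages drawn uniformly from a pool, fixed follow-up
offsets, piecewise means with group shifts, normal random effects,
residual noise, an optional normal TVC with missing-completely-at-random
masking (which satisfies MAR by construction), and optional per-cohort
parameter shifts. The baseline age doubles as a birth-cohort label.

`bmi_divergence_scenario()` encodes the package's reference setting:
Type II divergence with intercept 26.5 kg/m² at `a_ref = 25` yr, childhood
slope 0.67, slope change -0.49, change point 16.02 yr, group CP shift
12.37 yr, random-intercept variance 2.77, residual variance 2.47, baseline
ages {3, 6, 9, 12, 15, 18} (six birth cohorts), offsets
{3, 6, 9, 21, 27, 31} yr — six repeated measures per subject spanning ages
6–49, as in long-running cardiovascular cohort designs. Only a random
intercept is used in this scenario; that is the dominant person-level
variance component in BMI panels, and it keeps the reference setting
estimable at every sample size studied (100/100, 50/100, 30/100).

What the generator does *not* emulate: informative dropout, skewed or
heteroscedastic residuals, visit-age measurement error, or within-subject
trends in the TVC. Tests passing against this generator therefore certify
the estimation machinery under the stated model, not robustness to those
real-data features.

## Numerical choices

* Ages are centered at `a_ref` (dataset attribute; grand mean by default,
  25 yr in the reference scenario), but change points are always stored and
  reported on the raw age scale.
* Quantiles everywhere (posterior summaries, boxplot statistics) use R's
  default type-7 linear interpolation; whiskers follow
  `min(max(x), Q3 + 1.5 IQR)` / `max(min(x), Q1 - 1.5 IQR)`.
* Profile-likelihood ties and midway-rule ties both resolve to the smallest
  candidate, making every estimator deterministic given the data.
* A profile is declared "flat" (no detectable slope change) when no grid
  point improves on the straight-line fit by more than $10^{-10}$ of the
  total sum of squares — robust to exact-fit degeneracies where the
  log-likelihood is infinite.
* Degenerate inputs: an empty dataset runs prior-only (useful for
  validation); a zero-variance covariate refuses to standardize; an
  entirely missing TVC warns and leaves its coefficient at the prior.

## Problem sizes and protocols

The full-length protocol (4 chains, 50000 burn-in, 20000 kept, thin 10) is
the `bhpr_fit()` default and what we would run for a publication analysis.
For the packaged simulation studies and tests we use a reduced protocol —
2 chains, 5000 burn-in, 5000 kept, thin 5 for single-fit checks; 1 short
chain for replicate-heavy comparisons — because with ~1200 observations and
a profile-likelihood-anchored start the posterior means of this model
stabilize within a few hundred sweeps, and across-replicate averages
smooth the remaining Monte-Carlo noise. The recovery script
(`scripts/acceptance.R`) uses 20 replicates of the 100/100 scenario; the
test suite uses 5–20 replicates per property and 50 replicates per sample
size for the LS-means bias direction.

## Limitations

* One change point per trajectory; no smooth (bent-cable) transition.
* Gaussian residuals, homoscedastic and independent within subject; no AR1
  or t-errors.
* DIC focus is conditional only; WAIC/LOO are not provided.
* The Tukey family convention is the per-age contrast set; analysts wanting
  the full all-pairs family should adjust `nmeans` in `tukey_pairwise()`.
* MCMC for the change point is random-walk based: posteriors with widely
  separated modes (e.g. nearly flat profiles) will mix slowly and should be
  screened with `profile_loglik_cp()` first.
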