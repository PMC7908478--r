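---
title: "Latent neighborhood factors: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent neighborhood factors: models, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`neighborfactor` turns a wide tract-level demographic table into a small
set of oblique latent factors and quantifies how each factor relates to a
tract-level prevalence of poor mental health. This vignette is the
package's own account of the statistical machinery: the models and their
assumptions, the tunable parameters and why their defaults are what they
are, what the synthetic-data generator does and does not emulate, and the
numerical choices made where the design was genuinely open.

## The measurement model

The core assumption is the common-factor model. After transformation and
standardization, the p observed variables per tract are taken to satisfy

$$x = \Lambda f + \varepsilon, \qquad f \sim (0, \Phi), \quad
\varepsilon \sim (0, \mathrm{diag}(\psi)),$$

so the population correlation matrix is
$R = \Lambda \Phi \Lambda^\top + \mathrm{diag}(\psi)$ with pattern matrix
$\Lambda$ (p × k), factor correlations $\Phi$ (k × k), and uniquenesses
$\psi$. Factors are deliberately allowed to correlate — demographic
constructs such as affluence and racial composition are not orthogonal in
real cities — which is why an oblique rotation is used and why the factor
correlation matrix is itself a reported result.

**Extraction.** `fit_efa()` estimates uniquenesses by the minimum-residual
(unweighted least squares) criterion: it minimizes the sum of squared
*off-diagonal* residuals of $R - \Lambda\Lambda^\top$ over $\psi$, with
$\Lambda$ obtained from the leading k-dimensional eigenstructure of the
reduced matrix $R - \mathrm{diag}(\psi)$. Minres makes no multivariate
normality assumption and is well defined for correlation matrices that a
maximum-likelihood fit would reject. The optimizer is L-BFGS-B over
$\psi \in [0.005, 1]^p$, started at one minus the squared multiple
correlations.

**Rotation.** The unrotated solution is rotated by direct oblimin with
$\gamma = 0$ (quartimin), the common default in the factor-analysis
software family, via the oblique gradient-projection algorithm. Two
conventions make the output unique: factors are ordered by descending
variance explained ($\mathrm{diag}(\Phi \Lambda^\top \Lambda)/p$), and
each pattern column is signed so its largest-magnitude loading is
positive.

**Scores.** Per-tract factor scores use the regression (Thurstone) method,
$W = R^{-1} \Lambda \Phi$, applied to the standardized data. Regression
scores are biased toward zero relative to the true factors but maximize
correlation with them, which is the property the downstream association
analysis needs.

**Stability.** `bootstrap_loading_se()` resamples tracts with replacement
and refits the whole model. Because factor order and sign are arbitrary
across refits, each resample is aligned to the reference solution before
the per-loading standard deviation is taken: the column assignment
maximizing total absolute Tucker congruence is found by exhaustive search
over the $k!$ permutations (exact for the k ≤ 8 range this package
targets), with sign flips from the congruence signs. Without alignment,
bootstrap SEs confound sampling variability with label switching and are
meaningless.

## Choosing the number of factors

`factor_diagnostics()` reports three standard signals: the eigenvalues of
the observed correlation matrix with the Kaiser count (eigenvalues ≥ 1,
applied to the observed, not reduced, matrix); a scree elbow; and, per
candidate k, the fitted model's cumulative variance, RMS off-diagonal
residual, and off-diagonal fit
$1 - \sum \mathrm{res}^2 / \sum r^2$. The scree elbow is computed as the
point of maximum acceleration (largest discrete second difference) of the
*log* eigenvalue sequence, minus one. The log scale matters: on the raw
scale the first factor's dominance places the maximum curvature at the
second eigenvalue for essentially any correlated-factor structure, while
on the log scale the curvature peaks where the eigenvalues drop to the
noise floor — the boundary the elbow is supposed to mark. The final choice
of k remains a judgment call; the diagnostics inform it, they do not
automate it.

## Feature selection

Three rules reduce the raw table, in a fixed order that the removal logs
account for exactly:

1. **Redundancy** (`drop_redundant`) is *catalog-declared*, never inferred
   from correlations. The archetype is a female share that is one minus
   the male share: definitionally redundant. Auto-detection by correlation
   would silently change the analysis variable set on every data release,
   which is exactly the reproducibility failure this package exists to
   avoid.
2. **Low variability** (`filter_low_cv`) drops columns whose coefficient
   of variation — sample standard deviation (n − 1 denominator) over the
   mean, on raw untransformed values, ignoring missing cells — falls below
   0.06. A CV is only meaningful for positive-mean quantities; columns
   with mean ≤ 0 are exempt from the rule and logged as retained, never
   silently dropped.
3. **Strata combination** (`combine_strata`) collapses subgroup columns
   into one statistic per group: `sum` for additive shares (education
   levels into share-with-degree), `weighted_mean` with bin weights for
   ordered bins (age bands with midpoints into mean age). A missing value
   in any subgroup propagates, so imputation happens downstream on the
   combined statistic.

The CV threshold, and the choice of sample rather than population standard
deviation, are exposed as configuration; the defaults are the values the
pipeline was designed around.

## Transformation and imputation

Factor analysis of a correlation matrix is most defensible when marginals
are roughly Gaussian; census shares and dollar amounts are not.
`fit_transforms()` evaluates, per column, the applicable members of
{identity, log-shift, sqrt, logit, Yeo-Johnson} and picks the family
minimizing the absolute sample skewness of the transformed values.

Numerical details that matter:

* **Simplicity margin.** The earliest-listed family whose |skewness| comes
  within 0.10 of the minimum wins. Without the margin, Yeo-Johnson — whose
  free λ can drive *sample* skewness to zero exactly — would displace the
  structurally correct transform (e.g., the exact logit of a
  logistic-normal share) on finite-sample noise of order
  $\sqrt{6/n}$. With it, refitting on already-transformed data returns
  identity for every column: the fit–apply–fit fixed point the tests
  assert.
* **Domain edges.** Log and logit shifts use ε = half the smallest
  positive observed value; logit squeezes exact 0/1 to ε and 1 − ε.
  Applying a spec to a value outside its family's domain is an error
  naming the column and row, not a silent NA.
* **Standardization** constants (mean, SD of the transformed values) are
  recorded in the spec, so a fitted spec replays exactly on new data and
  the transformed fitting table has columns of mean 0, SD 1.

`knn_impute()` fills missing cells by the inverse-distance-weighted
average of the 10 nearest rows, with Euclidean distance over the columns
observed in both rows rescaled by $\sqrt{p / p_\mathrm{shared}}$ so that
sparse overlaps do not masquerade as proximity. Weights are
$1/(d + 10^{-8})$, so exact duplicates dominate without dividing by zero.
Observed cells are never modified; a missing cell whose entire
neighborhood lacks the column falls back to the column mean with a
warning. Imputation runs *after* transformation and standardization
because a Euclidean metric across columns presumes comparable scales.

## The association models

**Bivariate.** `state_spline_r2()` fits, per factor and per state, a cubic
smoothing spline of prevalence on factor score with the penalty chosen by
generalized cross-validation, and summarizes $R^2 = 1 -
SS_\mathrm{res}/SS_\mathrm{tot}$ by the median and IQR across states.
Separate state fits absorb regional differences in both level and shape.
States with fewer than 20 tracts (configurable) are excluded — a GCV
spline on a handful of points is an interpolator — as are states where the
spline cannot be fitted, each with a logged reason.

**Multivariable.** `decomposition_report()` fits, by maximum likelihood,
the null model (random state and nested county intercepts only), the
confounder-only model $M_a$, one model per factor $M_{a,i}$, and the full
model; `r2_from_variances()` converts variances to
$R^2 = (V_\mathrm{null} - V_\mathrm{model})/V_\mathrm{null}$, and the
factor-level summaries are the unique variance $R^2_{a,i} - R^2_a$ and
Cohen's $f^2 = (R^2_{a,i} - R^2_a)/(1 - R^2_{a,i})$, labelled
small/medium/large at 0.02/0.15/0.35 (a ≥ rule at each boundary).

Open choices resolved here, both configurable:

* **Which variance is V.** The package defaults to the *total* unexplained
  variance — the sum of state, county and residual components — so that a
  fixed effect explaining between-state structure registers in $R^2$. A
  residual-only definition is available (`variance = "residual"`).
* **ML, not REML.** Variance comparisons across models with different
  fixed effects are only coherent under ML; the monotonicity property
  (adding a fixed effect never decreases $R^2$) holds under ML and is
  asserted in the tests.
* County intercepts are nested within state (`(1 | state:county)`),
  because county codes are unique only within a state in FIPS-style
  keying. Prevalence is modelled on its own scale (identity link); at the
  prevalence levels involved the logit is locally linear, and the
  identity-link model is what the R²/f² formulas above presume.

## The synthetic-data generator

The generator is not a fixture factory; it defines the study conditions
under which the pipeline's claims are tested. `generate_truth()` draws a
simple-structure oblique model — each variable has one primary loading in
[0.55, 0.80] (at least 0.5 after communality control), cross-loadings
below 0.2, factor correlations uniform in [−0.4, 0.4] subject to positive
definiteness — and completes each variable's variance to one, so the
latent core columns are unit-variance normals.

`generate_tract_table()` then applies a fixed menu of marginal skew maps,
assigned round-robin: $e^{x/2}$ (income-like right skew), $(x+5)^2$
(squaring, shifted so the map is monotone — hence invertible — over the
effective range of a standard normal), $\mathrm{logis}(x-2)$ (a
minority-share-like proportion; the shift makes the marginal visibly
skewed so that the logit, rather than the identity, is its correct
inverse), and identity. It plants complement columns (1 − x), a
near-constant column (CV ≈ 0.005), a strata split whose subgroup shares
sum exactly to the parent, and MCAR missingness at rate 0.0016 — the
sparse-missingness regime of real census extracts.

`generate_outcome()` builds prevalence on the logit scale: baseline
`qlogis(0.12)` (a realistic poor-mental-health prevalence), per-factor
effects defaulting to a strong protective first factor (−0.8), a null
second factor, and moderate effects (0.30–0.45) thereafter — mirroring the
qualitative pattern the method is meant to expose: one dominant factor,
one null factor, several intermediate ones. State and county random
intercepts have SDs 0.15 and 0.10 and the residual SD is 0.15, all on the
logit scale; these are choices of plausible magnitude, not published
values. Confounders (age, sex ratio, race/ethnicity shares, poverty) are
noisy linear images of the factors with $R^2 = 0.5$ against the factor
space, so confounder adjustment genuinely attenuates factor effects — by
construction, the attenuation phenomenon is reproducible.

What the generator does *not* emulate, and what passing tests therefore do
not establish about real data: spatial autocorrelation between neighboring
tracts, survey margins of error, small-area-estimation artifacts in the
outcome, unbalanced geography (equal tracts per county is the default),
and any real FIPS coding. A real oblique factor draw can also cancel a
factor's *marginal* association while leaving its conditional effect
intact — the generator exhibits this honestly rather than hiding it.

## Problem sizes and determinism

The reference configuration used throughout the tests and the acceptance
script is 5 factors, 39 core variables, 5000 tracts in 20 states × 5
counties, with bootstrap stability assessed at 200 resamples; property
checks that need tighter sampling error use up to 20,000 rows with fewer
variables. These sizes were chosen so that the complete suite exercises
every stage at full methodological fidelity while remaining a
desk-scale computation.

Every stochastic step takes an explicit integer seed and restores the
caller's RNG state, so identical seeds reproduce byte-identical tables,
scores and artifacts. The oblimin rotation uses a deterministic set of ten
starts (identity plus nine fixed pseudo-random orthonormal starts) because
the identity start alone can sit exactly on a quartimin saddle point for
perfectly balanced structures; the lowest criterion value wins, keeping
`fit_efa()` a pure function of its inputs. Heywood cases are clamped to a
communality of 0.995 with a warning by default (`heywood = "stop"` to
abort instead); a singular correlation matrix in scoring is
ridge-regularized with λ = 1e−8 and a warning.

## Known limitations

* Redundancy must be declared in the catalog; the package will not detect
  an undeclared near-duplicate pair, which will instead inflate a factor.
* The transform menu is intentionally small; a variable whose best
  Gaussianizer lies outside it (e.g., a bimodal marginal) gets the least
  bad family, and no transform fixes multimodality.
* Regression scores are shrunken estimates of the factors; score–outcome
  associations are correspondingly conservative.
* The mixed-model R² definitions compare *estimated* variance components;
  with very few states the null-model variance itself is noisy and the
  decomposition inherits that noise.
* Effect-size labels apply hard thresholds to continuous quantities; an
  f² printed at the boundary (0.149 vs 0.15) changes label with its
  fourth decimal, which is a property of the rule, not of the data.
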