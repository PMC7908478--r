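# neighborfactor

Latent neighborhood factors from tract-level demographics, and their
association with the prevalence of poor mental health.

## The problem

Studies of how neighborhoods affect resident mental health measure "the
neighborhood" in wildly inconsistent ways — a single deprivation index here,
racial composition there — which makes results hard to compare. An
alternative is to let a wide, objective demographic table speak for itself:
take every tract-level statistic a census product provides, reduce it to a
handful of oblique latent factors by exploratory factor analysis, score
every tract on those factors, and then ask how much of the between-tract
variation in a health outcome each factor explains.

`neighborfactor` implements that pipeline end to end for tract-keyed CSV
inputs, and ships a synthetic-data generator with known ground truth so
every stage can be validated offline:

1. **Feature selection** — catalog-declared redundancy removal (a share and
   its complement carry one datum), a coefficient-of-variation filter
   (CV = s/x̄ < 0.06 across tracts drops near-constant variables), and
   combination of strata subgroups into single statistics (sums of shares,
   or bin-weighted means).
2. **Transformation and imputation** — per-variable Gaussianizing transform
   chosen from {identity, log-shift, sqrt, logit, Yeo-Johnson} by minimum
   absolute sample skewness, standardization, and weighted 10-nearest-
   neighbor imputation of missing cells in the standardized space.
3. **Factor model** — exploratory factor analysis with minimum-residual
   (ULS) extraction and direct oblimin (quartimin) rotation, giving a
   pattern matrix Λ, factor correlations Φ and uniquenesses ψ with
   R ≈ ΛΦΛᵀ + diag(ψ); factor-number diagnostics (Kaiser's rule, scree
   acceleration, variance explained, RMS residual, off-diagonal fit);
   regression (Thurstone) scores W = R⁻¹ΛΦ; bootstrap loading standard
   errors with congruence-based factor alignment.
4. **Association** — per-state cubic smoothing splines (penalty by GCV) of
   prevalence on each factor score, summarized by the median and IQR of R²
   across states; and a linear mixed-model variance decomposition with
   random state and nested county intercepts, fitted by ML. With
   R²_model = (V_null − V_model)/V_null, each factor's unique variance is
   R²_{a,i} − R²_a and its local effect size is Cohen's
   f² = (R²_{a,i} − R²_a)/(1 − R²_{a,i}), labelled small/medium/large at
   0.02/0.15/0.35.

## Worked example

Generate a synthetic study (5 factors, 39 core variables, 5000 tracts in 20
states) and run the full pipeline:

```r
library(neighborfactor)

study <- simulate_study(seed = 1)              # truth + tracts + outcome
sel   <- select_features(study$tracts, study$catalog)
specs <- fit_transforms(sel$table)
x     <- knn_impute(apply_transforms(sel$table, specs))
print(specs)
#> Transform specs for 39 variables:
#>    identity   log_shift        sqrt       logit yeo_johnson
#>           9          10          10          10           0
```

The selection stage keeps exactly the 39 core variables (3 planted
complements dropped as redundant, 1 near-constant column dropped at
CV < 0.06, one 4-way strata split recombined), and the transform stage picks
the exact inverse of every planted skew map. Fitting the factor model:

```r
model  <- fit_efa(x, k = 5)
#> variance explained: 0.1, 0.1, 0.1, 0.09, 0.09 (cumulative 0.48)
#> rms residual 0.0066, off-diagonal fit 0.9992
scores <- compute_scores(model, x)
state_spline_r2(scores, study$outcome)
#> Per-state smoothing-spline fits (R^2 across states):
#>    factor n_states median_r2 q25_r2 q75_r2
#>  factor_1       20     0.343  0.308  0.364
#>  factor_2       20     0.006  0.002  0.023
#>  factor_3       20     0.007  0.001  0.023
#>  factor_4       20     0.038  0.025  0.058
#>  factor_5       20     0.316  0.292  0.327
```

Five factors reproduce the off-diagonal correlation structure almost
exactly (off-diagonal fit 0.9992), and two factors dominate the bivariate
association with prevalence. Adjusting for the confounders with the
mixed-model decomposition:

```r
decomposition_report(study$outcome, scores,
                     grep("^conf_", names(study$outcome), value = TRUE))
#> Mixed-model variance decomposition (V_null = 0.02606 ):
#>   model                     label variance_explained unique_variance     f2 effect_label
#>      Ma          confounders only             0.6340              NA     NA         <NA>
#>    Ma,1    confounders + factor_1             0.6869          0.0529 0.1690       medium
#>    Ma,2    confounders + factor_2             0.6344          0.0004 0.0011         none
#>    Ma,3    confounders + factor_3             0.6355          0.0015 0.0041         none
#>    Ma,4    confounders + factor_4             0.6384          0.0044 0.0121         none
#>    Ma,5    confounders + factor_5             0.6972          0.0632 0.2086       medium
#>  Ma,1:5 confounders + all factors             0.7635          0.1295 0.5476        large
```

The two strong bivariate factors keep medium adjusted effects but are
attenuated by the confounders (which the generator builds as noisy images
of the factors), the factor generated with a zero outcome effect shows
essentially no unique variance, and all factors jointly have a large
effect — the qualitative pattern the pipeline is designed to expose.
Comparing the estimated pattern to the generating loadings gives per-factor
Tucker congruences above 0.99 and score–truth correlations above 0.93.

`run_pipeline(pipeline_config(), "tracts.csv", "catalog.csv",
"outcome.csv", "run1")` performs all of the above plus the bootstrap on
file inputs and writes every intermediate artifact and a reproducibility
manifest into a fresh run directory.

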