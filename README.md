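# hipshape

Statistical shape modeling of 2D proximal-femur outlines and hip-fracture
risk discrimination.

Low bone mineral density explains only part of hip-fracture risk; the
*shape* of the proximal femur — how the head, neck and trochanters are
proportioned — carries independent information about how loads travel
through the hip in a fall. `hipshape` is for researchers working with
landmark outlines digitized from hip radiographs who want to quantify that
shape signal and compare it, head to head, with BMD and classical geometry
as a fracture predictor.

## What it computes

Given per-subject outlines of $k$ ordered landmarks (default 60, lesser
trochanter around the head to the opposite shaft point, right hips) and a
covariate table:

1. **Generalized Procrustes alignment** removes translation, centroid-size
   scale and rotation (no reflections), with optional tangent-space
   projection at the mean.
2. **A PCA point-distribution model**: modes of variation $\Phi$,
   eigenvalues $\lambda_j$, and per-subject scores in SD units,
   $s_j = \phi_j^\top(x - \bar x)/\sqrt{\lambda_j}$ (mean 0, SD 1 over the
   cohort). Ten modes retained by default; a cumulative-variance target is
   the alternative rule.
3. **Femoral geometry** from the raw mm landmarks: head diameter
   (least-squares circle), neck width (minimal cross-section perpendicular
   to the neck axis), neck length (head center to the intertrochanteric
   line).
4. **Risk models**: logistic regression of incident fracture on shape
   modes, BMD, geometry and combinations, adjusted for age/BMI (and
   femoral-neck BMD for the per-mode table); Wald odds ratios with 95% CIs,
   in-sample AUROC with DeLong CIs, McFadden pseudo-R²; site-specific
   (femoral-neck / intertrochanteric) subsets and femoral-neck T-score
   strata.
5. **A random-relabeling null check**: case/control status reassigned at
   chosen case-to-control ratios; no mode should associate with shuffled
   labels.
6. **A synthetic cohort generator** — femur-like outlines with ten planted
   orthonormal modes (a designated "long neck / small head / narrow neck"
   mode among them), configurable eigenvalue spectrum and landmark noise,
   covariates with realistic case/control contrasts, and outcomes from a
   logistic model with planted per-SD odds ratios — so the entire pipeline
   is testable with no external data.

## Worked example

```r
library(hipshape)

cohort <- simulate_cohort(cohort_config(), seed = 1) # n = 399, 60 landmarks
alignment <- gpa_align(cohort$landmarks)
model <- shape_pca(alignment, n_modes = 10)
model
#> Point-distribution model
#>   landmarks: 60  subjects: 399
#>   retained modes: 10 of rank 116
#>   variance captured: 97.8%

scores <- score_shapes(model, alignment)
data <- dplyr::left_join(scores, cohort$subjects, by = "subject_id")
fit <- fit_fracture_model(data, paste0("mode", 1:10),
  adjust = c("age", "bmi", "bmd_fn")
)
dplyr::filter(tidy(fit), term == "mode4")
#> # A tibble: 1 × 8
#>   term  estimate std.error statistic  p.value odds.ratio conf.low conf.high
#>   <chr>    <dbl>     <dbl>     <dbl>    <dbl>      <dbl>    <dbl>     <dbl>
#> 1 mode4     1.00     0.146      6.88 5.92e-12       2.73     2.05      3.63
```

The ten modes capture 97.8% of aligned-shape variance, and the fourth
mode — planted with a per-SD log-odds of log(2.48) — is recovered with an
odds ratio of 2.73 (95% CI 2.05–3.63) per SD at this cohort size; at
n = 5000 the estimate tightens to within a few percent of the planted
value. `run_pipeline()` performs all of the above plus the geometry,
comparison, stratification and permutation tables in one seeded,
reproducible call, and `plot_mode_gallery()` / `autoplot()` draw the
mean-shape ±2 SD outlines for each mode.

See `vignettes/shape-fracture-methods.Rmd` for the model, its assumptions,
and what the synthetic cohort does and does not emulate.

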