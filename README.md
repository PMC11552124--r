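# felmorph

Digital nuclear morphometry for breast fibroepithelial lesions (FELs).

FELs span common benign fibroadenomas (FAs) and rare phyllodes tumours
(PTs); PTs are graded benign, borderline or malignant on stromal
histology. The grading criteria overlap and are read subjectively, with
marked inter-observer variability at the benign end of the spectrum.
`felmorph` implements an objective, image-derived alternative: stromal
nuclei are segmented from brightfield immunohistochemistry tiles
(hematoxylin counterstain; DAB marking cytokeratin/LCA-positive epithelium
and leukocytes, which are excluded), six shape descriptors are measured per
nucleus in calibrated micrometre units, aggregated per case, and combined
into logistic nuclear-morphology scores.

The pipeline, module by module:

1. **Stain separation** — Beer–Lambert optical density
   `OD_c = log10(I0 / I_c)` per RGB channel, unmixed into hematoxylin, DAB
   and residual strengths by inverting a 3×3 unit-norm stain matrix
   (Ruifrok-style H-DAB vectors by default, configurable via JSON).
2. **Nucleus segmentation** — Gaussian smoothing, hematoxylin-OD
   thresholding, watershed splitting on the distance transform, half-max
   boundary refinement, area filtering, and per-nucleus DAB exclusion.
3. **Morphometry** — per nucleus: area (µm²), perimeter (µm), circularity
   `4π·area/perimeter²`, maximum and minimum caliper (Feret) diameters via
   rotating calipers on the convex hull, and eccentricity
   `√(1 − (b/a)²)` of the moment-equivalent ellipse. Per case: mean,
   median and range of each feature.
4. **Scoring** — nuclear-morphology score `β₀ + Σ βᵢxᵢ` on per-case mean
   features. Two fitted models ship as JSON: PT grading (benign vs
   borderline/malignant, cutoff −0.2008) and FA vs benign PT (cutoff
   −1.0596), plus a single-feature circularity model (cutoff 0.698) for
   recurrence stratification.
5. **Cohort statistics** — Mann–Whitney comparisons, ROC/AUC via the
   rank-sum identity with Hanley–McNeil confidence intervals, Youden-J
   cutoff selection, screened multivariate logistic fitting, Kaplan–Meier
   event-free survival and log-rank tests.
6. **Synthetic data** — rendered H-DAB tiles of elliptical nuclei with
   closed-form ground truth, and per-case feature cohorts with prescribed
   group means/SDs and survival outcomes, so every stage is testable
   without patient material.

## Worked example

Render a synthetic tile with 60 stromal and 15 DAB-positive nuclei, run
the full measurement chain, aggregate, and score:

```r
library(felmorph)

scene <- generate_tile_scene(n_stromal = 60, n_dab_positive = 15,
                             tile_um = 140, seed = 42)
tile  <- render_tile(scene, pixel_size = 0.25)
res   <- measure_tile(tile)
res$segmentation
#> labeled_segmentation: 75 nuclei (15 DAB-excluded) on 560 x 560 px

case <- summarize_case(res$features, "demo_case")
case[, c("feature", "mean", "median", "min", "max", "n")]
#>          feature   mean median    min    max  n
#> 1       area_um2 17.628 17.449 12.823 25.003 60
#> 2   perimeter_um 15.995 16.126 13.322 18.517 60
#> 3    circularity  0.863  0.858  0.711  0.983 60
#> 4 max_caliper_um  6.547  6.552  4.795  7.911 60
#> 5 min_caliper_um  3.465  3.410  2.724  4.632 60
#> 6   eccentricity  0.837  0.858  0.565  0.934 60

means <- setNames(case$mean, case$feature)
m <- pt_grading_model()
s <- nuclear_morphology_score(as.data.frame(t(means)), m)
sprintf("grading score %.3f -> %s (cutoff %.4f)",
        s, classify_score(s, m), m$cutoff)
#> "grading score -12.355 -> benign-like (cutoff -0.2008)"
```

All 75 rendered nuclei are detected, the 15 DAB-positive ones are
excluded, and the retained per-case mean area (17.6 µm²) sits within a
few percent of the scene's analytic ellipse truth. The grading score is
deeply benign-like: rendered ellipses are smoother and rounder
(circularity 0.86) than real stromal nuclei (cohort means ≈ 0.69), and
the circularity coefficient is negative, so idealised synthetic shapes
score well below the cutoff.

Cohort-level machinery works the same way on feature tables:

```r
coh <- generate_feature_cohort(n_per_group = 100, seed = 1)
coh <- attach_survival(coh, survival_sim_params(seed = 1))
fit <- fit_logistic_score(coh, coh$group == "FA")
ra  <- recurrence_analysis(coh)   # circularity cutoff 0.698
```

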