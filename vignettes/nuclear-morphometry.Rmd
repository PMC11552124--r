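---
title: "Nuclear morphometry of fibroepithelial lesions: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nuclear morphometry of fibroepithelial lesions: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(felmorph)
```

## The measurement problem

Grading of breast fibroepithelial lesions (FELs) rests on stromal
histology read by eye: cellularity, atypia, mitoses, borders. These
criteria form a continuum, and distinguishing a cellular fibroadenoma
(FA) from a benign phyllodes tumour (PT), or a benign from a borderline
PT, is notoriously variable between observers. `felmorph` operationalises
one objective alternative: measure the *shape of stromal nuclei* on
routine immunohistochemistry (IHC) sections and summarise it into linear
diagnostic scores.

The sections this pipeline consumes are hematoxylin-counterstained IHC
slides in which a cytokeratin + leukocyte-common-antigen antibody
cocktail deposits brown DAB chromogen on every epithelial cell and
leukocyte. Stromal nuclei — the diagnostic compartment — are exactly the
DAB-negative, hematoxylin-positive objects, which is what makes a fully
automated measurement loop possible.

## Stain model

Brightfield absorbance follows Beer–Lambert. For background intensity
$I_0$ (255 for 8-bit scans) the optical density per channel is

$$\mathrm{OD}_c = \log_{10}\!\frac{I_0}{\max(I_c, \varepsilon)},$$

with $\varepsilon$ = 1 intensity count guarding the logarithm (a pure
black pixel maps to OD $\log_{10}255 \approx 2.41$). Log base 10 is the
convention of the H-DAB deconvolution literature. OD is linear in stain
concentration, so a pixel's OD vector is a non-negative mixture
$\mathrm{OD} = M s$ of unit-norm stain vectors (columns of $M$), and
`deconvolve_stains()` recovers $s$ by inverting $M$. The default H and
DAB vectors are the standard Ruifrok–Johnston values; the third column
completes the basis as their normalised cross product. Scanners differ,
so the vectors are plain JSON configuration
(`inst/extdata/hdab_stain_vectors.json`), not constants. Negative
unmixed strengths (noise outside the stain simplex) are clipped to zero
and the clipped fraction is reported as a diagnostic.

## Segmentation

`segment_nuclei()` is a threshold-plus-watershed detector in the style of
QuPath's cell detection:

1. Gaussian smoothing of the hematoxylin strength map at `smoothing_um`
   (default 0.5 µm);
2. foreground where smoothed OD ≥ `h_threshold` (default 0.1 OD);
3. marker-based watershed on the distance transform of the foreground to
   split touching nuclei;
4. half-max boundary refinement (below);
5. removal of components outside 5–100 µm² (debris and clumps);
6. `exclude_dab_positive()` flags any nucleus whose mean DAB OD exceeds
   `dab_threshold` (default 0.2 OD); only unflagged nuclei enter
   morphometry.

The exact threshold values in a clinical deployment are scanner- and
protocol-specific calibrations; all are fields of
`segmentation_params()` with the defaults above.

**Half-max refinement.** A threshold fixed well below nuclear intensity
(needed for reliable *detection*) places the measured boundary where the
*smoothed* edge profile crosses that threshold — roughly one smoothing
scale outside the true stain boundary, inflating areas by tens of
percent. For a step edge blurred by a Gaussian, the half-maximum contour
coincides with the true edge location independent of the blur scale, so
each detected nucleus is re-thresholded at half its peak OD. Because the
residual displacement of a *curved* edge grows with the square of the
blur scale, the refinement map uses a lighter blur (`edge_smoothing_um`,
default half of `smoothing_um`) than the detection map. On rendered
test scenes this two-scale scheme brings every mean feature within ~2%
of the analytic truth, against roughly −40% area error for the raw
threshold mask.

**Region of interest.** In practice pathologists outline the stromal
tumour areas; `segment_nuclei(roi = ...)` accepts such a mask and keeps
nuclei whose centroid falls inside. Whole-slide extents are covered by
`tile_grid()` (2000 µm tiles, edge tiles truncated), and
`assign_tile()` assigns each nucleus to exactly one tile by centroid so
per-tile counts sum to slide totals.

## The six descriptors

For each retained nucleus, `compute_nucleus_features()` reports, in
calibrated units:

| feature | definition |
|---|---|
| area | polygon area of the traced boundary (µm²) |
| perimeter | boundary length (µm) |
| circularity | $4\pi \cdot \mathrm{area}/\mathrm{perimeter}^2$; 1 for a disk |
| max caliper | convex-hull diameter (µm) |
| min caliper | minimal width over hull edge directions (µm) |
| eccentricity | $\sqrt{1-(b/a)^2}$ of the moment-equivalent ellipse |

Numerical choices that matter:

* **Boundary tracing and perimeter bias.** Circularity is quadratically
  sensitive to perimeter error, and a raw 8-connected pixel chain
  overestimates the perimeter of a smooth shape by up to ~8%. The traced
  contour (pixel centres) is therefore smoothed by a circular moving
  average of its vertices (window 5) before measurement, which removes
  the staircase without shifting the boundary systematically.
* **Half-pixel parallel-body correction.** Traced vertices are pixel
  centres and sit about half a pixel inside the true stain boundary. The
  corrected measurement is the outward parallel body at distance ½ px:
  perimeter gains $\pi$ px and area gains $P/2 + \pi/4$ px². The
  algebra guarantees $4\pi A' \le P'^2$ whenever the uncorrected polygon
  satisfies it — and every simple polygon does — so measured circularity
  can never exceed 1. Calipers get the analogous ½ px correction, taken
  on the *raw* contour hull because vertex smoothing clips
  high-curvature tips and would bias the maximum caliper low.
* **Eccentricity from moments.** Verbal shape anchors (0 for a circle,
  1 in the degenerate limit) do not pin down one formula; the package
  adopts the standard regionprops definition via second-order central
  moments of the pixel mask, which is consistent with observed
  stromal-nucleus magnitudes (~0.78–0.81). A polygon-moment route
  (exact Green's-theorem integrals) is available for vector inputs.
* **Degenerate inputs.** Collinear polygons yield min caliper 0 with a
  warning; empty masks and zero-area polygons are errors; a case with
  zero retained nuclei cannot be aggregated and `summarize_case()` says
  so explicitly rather than returning NaNs.

On ellipse fixtures all six features converge to the closed forms as
pixel size shrinks, and at the working resolution of 0.25 µm/px agree
within 5% (tests `test-morphometry.R`, `test-pipeline.R`).

## Scores and classification

The diagnostic score is the linear predictor
$\beta_0 + \sum_i \beta_i x_i$ over per-case **mean** features in raw
calibrated units — no standardisation, since the shipped coefficients
are only meaningful on that scale. Means (not medians) are used because
the reference group summaries are reported as mean ± SD. Ties at the
decision cutoff go to the high class. Three models ship as JSON under
`inst/extdata/`: PT grading (cutoff −0.2008), FA vs benign PT (cutoff
−1.0596; scores at or above the cutoff are FA-like, an orientation
implied by the coefficient signs), and the single-feature circularity
model (cutoff 0.698) used for recurrence stratification. The cutoffs are
shipped constants from the original model fits; re-deriving them needs
the original cohort, which is not public, but `fit_logistic_score()`
re-runs the whole fitting recipe (univariate screen at p < 0.100, then
multivariate logistic, Wald p values, Youden cutoff) on any cohort —
synthetic ones included.

`contingency_metrics()` reports two families of percentages from a
score-class × diagnosis table, because published diagnostic tables mix
them: within-row (predictive-value-style) fractions, printed with
one-decimal truncation, and conventional column-wise
sensitivity/specificity. Both are returned, clearly named, and the
truncation behaviour is a documented flag (`method = "round"` for
conventional rounding).

## Cohort statistics

Group differences use two-sided Mann–Whitney tests
(`stats::wilcox.test` conventions: exact for small untied samples,
tie-corrected normal approximation otherwise). AUC is computed by the
rank-sum identity $U/(n_1 n_0)$ with midrank ties — an identity the test
suite asserts on every input — with Hanley–McNeil confidence intervals;
"best" cutoffs maximise Youden's J over midpoints between adjacent
distinct scores, ties broken toward the midpoint of the class means.
Survival uses the product-limit estimator with Greenwood variance and
the standard two-group log-rank statistic (`survival::survfit` /
`survdiff` under the hood, cross-checked in tests against hand
product-limit arithmetic and an independent O−E/V summation).
`recurrence_analysis()` dichotomises at the circularity cutoff and runs
the comparison overall and within each grade stratum that has both arms.

## What the synthetic generator does and does not emulate

Two generators stand in for patient material.

**Tiles.** `generate_tile_scene()` places non-overlapping ellipses
uniformly in a tile; stromal nuclei carry hematoxylin only, DAB-positive
nuclei (the epithelium/leukocyte stand-in) carry both stains.
`render_tile()` inverts the stain model exactly (Beer–Lambert, 8-bit
quantisation on by default, optional Gaussian sensor noise off by
default so oracles stay tight). Ellipses are chosen because every
descriptor has a closed form — area $\pi ab$, Ramanujan perimeter,
calipers $2a, 2b$, eccentricity $\sqrt{1-(b/a)^2}$ — giving the whole
render → deconvolve → segment → measure chain an analytic oracle.
Default semi-axes (3.3 × 1.75 µm) reproduce benign-PT-like caliper
magnitudes. The generator deliberately does *not* emulate chromatin
texture, tissue architecture, overlapping nuclei in 3-D, or scanner
artefacts; passing its tests demonstrates correct geometry and stain
algebra, not segmentation robustness on real slides.

**Cohorts.** `generate_feature_cohort()` draws per-case mean features
from a multivariate normal per diagnostic group, with group means/SDs
from `fel_reference_groups()` (FA n=59; benign/borderline/malignant PT
n=149/66/26). Published group summaries carry no between-feature
covariance, so the correlation model is a stated assumption: size
features correlated at 0.6, circularity–eccentricity at −0.5, size and
shape independent (`default_feature_correlation()`, any positive-definite
replacement accepted). `attach_survival()` adds exponential event times
with hazard $\lambda_0 \exp(\beta_c (x - \bar x))$ on circularity —
exponential so that medians stay analytic — and uniform censoring on
1–110 months (mean ≈ 55, matching a realistic follow-up). The default
baseline hazard 0.0023/month corresponds to ~21 events in 169 cases over
that window; the default circularity log-hazard of 25 per unit (≈ 0.5
per SD of 0.02) gives a clearly detectable, not overwhelming, effect.
These are simulation conditions chosen once, not fitted quantities.

## Problem sizes and verification

The test suite verifies: exact hand-oracle arithmetic (OD values,
3×3 unmixing, score values at group means, printed table percentages);
rotating calipers against a dense projection-direction oracle at 1e−6;
the isoperimetric bound on every measured nucleus; end-to-end recovery
on 110-nucleus scenes (exact counts, exact DAB exclusion, mean features
within 5%); cohort means within 3 standard errors at n = 10 000 per
group; Mann–Whitney and log-rank type-I error at nominal level under
null Monte-Carlo generators (3–4k and 1–1.5k replicates); and logistic
coefficient recovery within 3 SE at n = 5 000. These sizes were chosen
to give stable Monte-Carlo margins while keeping a full run around two
minutes on a laptop core.

## Known limitations

* Real stromal nuclei are not ellipses; the synthetic oracle validates
  the measurement chain, not biological fidelity. Scores computed on
  rendered tiles land far on the benign-like side because idealised
  ellipses are much more circular than real nuclei.
* Stain vectors are fixed per run; no automatic stain estimation
  (Macenko/Vahadane) is attempted.
* Whole-slide formats (SVS) are out of scope; the pipeline consumes
  exported tiles.
* The shipped model coefficients and cutoffs are frozen from their
  original fit; applying them to differently calibrated measurements
  (other magnification, other segmentation parameters) shifts feature
  scales and invalidates the cutoffs.
* Survival simulation assumes one record per case and independent
  uniform censoring; paired primary/recurrent samples from one patient
  are not modelled.
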