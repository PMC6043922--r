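---
title: "Functional spatial analysis of multiplexed images: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional spatial analysis of multiplexed images: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the statistical models implemented in `spatialgf`,
the choices made where the design was genuinely open, and what the
built-in simulator can and cannot tell you about real tissue.

## From marker panel to marked point pattern

A multiplexed immunofluorescence image is reduced to a marked point
pattern: per-cell coordinates in a rectangular observation window plus a
set of phenotype labels gated from six boolean markers. The seven
phenotypes are nested by construction — a CD3+CD8+ cell is both a T cell
and a cytotoxic T cell, and it is counted in both. Cells matching no
gating rule stay in the pattern but enter no count, curve or index; the
panel defines which populations are quantified, and unidentified cells
carry no interpretable label.

Coordinates are stored in microns with the raster convention (origin
top-left, y downward, 0-based, continuous). Inputs may declare pixel
units; they are scaled by the window resolution (default 1.57 µm/pixel).
Pixel-threshold equivalences are reported as `round(r / resolution)`,
which maps 32 µm to 20 px and 24 µm to 15 px; published pixel
equivalences of larger distances are not always self-consistent, and we
do not attempt to imitate any particular rounding beyond this rule. The
window defaults to the standard 2100 × 1600 µm field; a bounding-box
fallback exists behind an explicit flag because it biases boundary
corrections and should be a last resort.

## The G-cross function and its boundary corrections

For reference type *i* and target type *j*, `gcross()` estimates
G(r) = P(nearest type-*j* neighbour of a typical type-*i* cell ≤ r) on a
grid of 201 equally spaced distances on [0, r_max]. The dense grid makes
the trapezoidal integration error of the downstream area summaries
negligible at these scales; it is configurable. Nearest-neighbour
distances exclude the cell itself when one cell carries both phenotypes,
and distinct coincident cells register at r = 0.

Distances are censored by the image boundary, so three estimators are
offered:

* **none** — the raw empirical CDF of the per-reference nearest-target
  distances. It is the estimator the closed-form CSR check and the
  brute-force oracle tests target, and it is negatively biased near the
  border.
* **border** — the reduced-sample estimator, which at each r uses only
  reference cells at least r from the boundary. Its risk set can empty
  out and the raw ratio need not be monotone; we fill empty-risk values
  by last observation carried forward and restore monotonicity with a
  cumulative maximum, since a nearest-neighbour CDF is non-decreasing by
  definition.
* **km** (default) — the Kaplan–Meier product-limit estimator treating
  the distance to the boundary as a right-censoring time, with events
  ordered before censorings at ties. Censoring-based corrections are the
  standard default for nearest-neighbour summaries in spatial statistics;
  the choice is exposed because analyses differ, and all three agree
  exactly on patterns whose cells lie ≥ r_max from the boundary (a
  property the test suite asserts).

Curves with an absent reference or target phenotype are *undefined*
rather than an error: the estimate is NA, the curve carries
`defined = FALSE`, and downstream features become 0 with a missingness
flag. The zero reflects that no infiltration was observed at any
distance; the flag preserves the distinction from a genuine zero for
models and audits.

## Area summaries

`simple_auc()` integrates the piecewise-linear curve over [0, r_max]
(trapezoid; limits off the grid are handled by interpolating the end
points, so areas are exact for the stored polyline). The default is the
unnormalised area in µm — random forests are invariant to monotone
per-feature rescaling, so normalisation cannot change any downstream
ranking; a normalised variant is available. `kbins_auc()` partitions
[0, r_max] into K equal-width bins and integrates each; by construction
the bin areas sum to the simple area to floating-point precision, which
the suite checks to 1e−9 relative over random monotone curves.

Task defaults follow the grade-classification setting r_max = 32 µm with
K = 7, and the progression setting r_max = 24 µm with K = 14, sharing one
r_max across the simple, K-bins and MFPCA summaries of a task; both are
plain arguments.

`morisita_horn()` is the quadrat-based Morisita–Horn overlap,
MH = 2Σx_q y_q / ((Σx_q²/X² + Σy_q²/Y²)·X·Y) over square quadrats
(default side 100 µm, the scale of the distances probed; partial edge
quadrats included). It is symmetric, lies in [0, 1], and is NA when a
population is absent.

## Two-step multivariate functional PCA

The P×K bin-area block (P = 12 interactions in canonical order) is
compressed in two steps. Step 1, per interaction: centre the K columns
and eigendecompose the K×K covariance with uniform quadrature weights
(the bins share one width, so uniform weights are the natural quadrature
rule). All components with eigenvalue above 1e−12 of the leading one are
kept — step 1 decorrelates bins essentially losslessly, so the variance
cut is the sole responsibility of step 2; this keeps the single "95 %"
knob meaningful. Step 2: stack the univariate scores of all interactions
and eigendecompose their covariance; the multivariate scores are the
projections onto the resulting orthonormal combination weights, and k is
the smallest component count whose cumulative eigenvalue fraction
reaches the threshold (default 0.95). `fixed_k` overrides the rule when
a preset score dimension is wanted for comparability.

Numerical conventions: eigenvector signs are fixed by making the
largest-magnitude entry positive (so fits are reproducible up to
nothing); a zero-variance block yields k = 0 with a warning; n < 3
images is an error. Masked entries (absent phenotypes) are excluded from
the centring means and treated as sitting at the mean, so structural
zeros cannot drag element means toward zero. With a single element and
everything retained, the procedure reduces exactly to ordinary PCA — one
of the property tests.

## Classification, cross-validation, importance

Each ensemble member is a 500-tree random forest (bootstrap resampling,
√d features per split, probability = fraction of trees voting positive)
on one feature block: MFPCA scores, raw bins, simple areas, counts, or
Morisita–Horn. Cross-validation is leave-one-group-out; the unit
defaults to the image, matching per-image evaluation conventions, but
the patient unit is recommended and is what the package's own benchmarks
use — images of one patient are correlated, and holding out whole
patients both rules out leakage and cuts the fold count (29 folds
instead of 230 on the stock cohort), which is also why the benchmark
suite stays fast. Every fit-time statistic, including the MFPCA basis,
is refitted inside each training fold; a paper-style global fit would
leak the held-out image into its own transform. A training fold
collapsing to one class predicts its class prevalence with a warning.

Member probabilities are combined by unweighted averaging (weights are
exposed, but a symmetric mean is the default because nothing in the
problem privileges a member a priori). AUC is the Mann–Whitney
probability with ties counted ½; confidence intervals use the DeLong
variance by default (deterministic given the data) with a stratified
bootstrap alternative; the test against chance is one-sided on the
DeLong z-statistic.

Per-interaction importance for an ensemble containing MFPCA features is
not uniquely defined, because components mix interactions. The package
uses grouped permutation: one shared random row permutation is applied
across images to all K bin columns of interaction p, each fold's frozen
transform and model re-predict their held-out images, and the importance
is 100 × the mean drop in out-of-fold accuracy (threshold 0.5, ≥ 0.5
classed positive) over R = 20 permutations. Members that do not consume
the bin block (counts, Morisita–Horn, simple areas) keep their baseline
predictions. Ties in the ranking are broken by the canonical interaction
order, making the table deterministic. Two consequences worth knowing:
a constant or label-independent interaction scores ≈ 0, and when a
classifier is perfectly separated with a wide margin, permuting one
interaction may flip nothing — importance magnitudes are only
informative when accuracy is below the ceiling.

## What the simulator emulates, and what it does not

`simulate_cohort()` mimics the structure of a graded surgical series:
29 patients by default, every patient with ~5 low-grade images and 17
"mixed" patients with 5 additional high-grade images (230 images), in a
2100 × 1600 µm window. Epithelium follows a Thomas-type cluster process
(5 uniform cluster centres, Poisson(35) offspring, 40 µm Gaussian
spread — a few hundred epithelial cells per image, compact papillary
clusters). Each immune cell is, with probability θ, placed at an
Exponential(τ) distance (default τ = 15 µm) and uniform angle from a
uniformly chosen epithelial cell (redrawn until inside the window), else
uniformly in the window. The attraction mixture directly parameterises
what the G-cross function measures, so θ produces monotone, predictable
infiltration signatures; default intensities (T cells 6e−5/µm²,
macrophages 3e−5/µm²) give a few hundred immune cells per image, and
marker positivities (CD8 0.35, PD-1 0.25, PD-L1 0.25–0.3) are moderate
so every phenotype is populated. These sizes keep a full 29-patient
cohort build under a minute.

Three stock benchmarks fix the study conditions for validation:
*separable* (θ for T cells 0.2 vs 0.8 between grades, with modestly
higher T-cell intensity in high grade, so spatial and count members both
carry signal), *null* (identical parameters, for calibration), and
*planted* (only the CD8− PD-1− T-cell subpopulation changes attraction
between grades; PD-L1 positivity is kept rare so the PD-L1+ reference
subsets — which share targets with their parent phenotypes and are
therefore intrinsically correlated with them — carry little independent
information, concentrating the signal in the epithelium→T-cell
interaction).

The simulator is deliberately not a tissue model: no duct or papilla
geometry, no stromal/epithelial compartment boundaries, no segmentation
or phenotyping error, no inter-patient heterogeneity beyond Poisson
noise, and independence between immune cells given the epithelium.
Passing the benchmark suite therefore demonstrates that the estimators,
the compression and the evaluation machinery behave correctly under
known ground truth — not that any particular AUC is attainable on real
cohorts, whose spatial structure is richer and whose effect sizes are
smaller.

## Problem sizes used by the tests

Unit tests run on miniature cohorts (8 patients, 2 images per region,
~700 × 500 µm windows) chosen so each exercises its contract in seconds.
The statistical validation suite uses the full 29-patient benchmarks:
200 Poisson simulations for the closed-form check, 10 separable and 20
null cohorts for power and calibration, and 20 planted cohorts for
importance recovery, all under leave-one-patient-out cross-validation
with the forest and permutation settings described above. The
acceptance script (`scripts/acceptance.R`) recomputes one instance of
each from a single seed.

## Known limitations

* The border estimator's monotonisation (LOCF + cumulative maximum) is a
  pragmatic repair; the KM default avoids the issue.
* Importance attribution through MFPCA components is one defensible
  operationalisation among several; magnitudes depend on the ensemble
  margin as noted above.
* Undefined-curve features are zero-imputed with a mask; models other
  than trees may prefer explicit missing-value handling.
* The progression task labels every low-grade image of a mixed patient
  positive; with image-level grouping this invites within-patient
  leakage, which is why patient grouping is recommended throughout.
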