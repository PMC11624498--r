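---
title: "Methods: multiscale dermal microvascular morphometry and PORH reactivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multiscale dermal microvascular morphometry and PORH reactivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`rsomvasc` quantifies the dermal microvascular network in volumetric
raster-scan optoacoustic mesoscopy (RSOM) images and follows its reactivity
during a post-occlusive reactive hyperemia (PORH) challenge. The pipeline
starts at reconstructed dual-frequency-band volumes — a low band
(10–40 MHz, dominated by larger microvessels) and a high band
(40–120 MHz, smaller microvessels) on the same grid — and proceeds through:

1. **Skin-layer segmentation**: per-column detection of the skin surface
   from the summed-band depth profile, then a fixed-thickness epidermis band
   and a fixed-depth dermis (DE) band below it.
2. **Vessel segmentation**: per-band Otsu thresholding inside the DE,
   union of the band masks, removal of small connected components.
3. **Skeleton morphometry**: 3D curve skeletonization of the vessel mask,
   branch/junction graph extraction, and 18 morphometric features grouped
   into three scales of detail.
4. **PORH dynamics**: per-feature percentage changes of the five
   post-baseline timepoints relative to baseline, per-feature and per-scale
   two-group statistics.
5. **Disease index**: per-timepoint leave-one-subject-out (LOSO)
   classification with in-fold univariate top-k feature selection and a
   probability random forest; the out-of-fold class-1 probability is the
   subject's feature-based index.
6. **Confounding analysis**: per-confounder nested logistic triplets
   (confounder; + index; + interaction) compared by residual deviance and
   likelihood-ratio tests, plus a multivariate linear probability model.

Because clinical recordings are not distributed with the package, a phantom
module generates ground-truthed vessel trees, dual-band volumes, PORH time
series and feature-level cohorts; every stage of the pipeline is validated
against these synthetic objects.

# The PORH protocol encoded in the data model

A measurement is six volumes per subject in fixed order: `baseline`, three
minutes of arterial occlusion (`occl1`–`occl3`), and two minutes of
hyperemia after cuff release (`hyp1`, `hyp2`). Reactivity is always
expressed as `100 * (f_t - f_baseline) / f_baseline`, five values per
feature and subject. Entries with a zero or missing baseline are treated as
missing data, not errors, and excluded pairwise downstream: a percentage
change of an undefined mean is itself undefined.

# The 18 features and the scale map

Feature definitions are in `?extract_features`; names, units and scale
labels in `feature_names()`, `feature_units()`, `feature_scales()`. The
scale-of-detail map is a package default stored as data and overridable
wherever a `scale_map` argument exists:

* **micro** (`f1`–`f6`): single-vessel parameters — junction angle, branch
  length, tortuosity, length-to-width ratio, diameter, volume.
* **meso** (`f7`–`f13`): network organization — branch count, junction
  density, vascular density, junctions-to-vessels ratio, J2J/J2E branch
  counts, junction count.
* **macro** (`f14`–`f18`): whole-layer parameters — DE thickness, total
  vessel area (en-face projection), mean signal in vessels and in the DE,
  DE area (side projection).

Two projection conventions were genuinely open: the total vessel area uses
the en-face (depth) projection and the DE area the `(z, x)` side view,
mirroring how cross-sectional displays are usually presented; both are
configurable and documented rather than hard-coded assumptions about the
original instrument software.

# Skeletonization: design and numerical choices

No installed R package offers 3D curve thinning, so the package implements
it in C++ from the topological characterization of simple points: a
foreground voxel is deletable when its foreground 26-neighbours form one
26-connected component and the background face-adjacent part of its
18-neighbourhood forms one 6-connected component. Deletion proceeds in six
directional subiterations (one face direction per pass) so at most one
voxel layer is removed per direction per cycle; within a pass, candidates
are deleted sequentially — re-checking simplicity at deletion time — in
increasing order of the Euclidean distance transform (EDT), which keeps the
skeleton centred. Voxels with at most one foreground neighbour (curve
endpoints) are never deleted.

Known degenerate input: a tube whose cross-section is exactly symmetric
about a voxel corner (an even-width digital disk) has no unique medial
line, and homotopic thinning — including the standard reference
implementations of 3D thinning — collapses such a tube. Continuous random
centerlines never hit this configuration; the phantom builders therefore
place deterministic test geometries at voxel centres.

Downstream graph construction classifies skeleton voxels by neighbour
count (1 endpoint, 2 slab, ≥3 junction), clusters adjacent junction voxels
into nodes (centroid position), traces slab chains into branches, and
derives per-point radii from the EDT of the original mask. Spur branches
shorter than `prune_um` (default 50 µm) are removed and the graph
re-derived, dissolving degree-2 nodes; junction nodes connected by branches
shorter than two voxels are merged. Tie-breaks in tracing follow
lexicographic voxel order, so the graph is deterministic.

Branch length is measured on the voxel chain after Gaussian-weighted
smoothing (window 9 points, sigma 2 points, endpoints fixed). The window
was chosen from the geometry phantoms before freezing: voxel staircase
inflates raw chain length by 2–5 % for oblique curves, while too much
smoothing shortens high-curvature arcs; window 9 keeps a straight tube at
tortuosity 1.000, a semicircle within 0.02 of pi/2, and a helix within 2 %
of its closed-form length per covered axial span. Skeletons of tubes
retract by about one radius at each end (the thinning erodes blunt caps
until the line's endpoints form); the phantom rasterizer stamps tubes as
capsule chains with rounded ends, which compensates this retraction almost
exactly, and phantom-based length checks normalize by the covered span.

# Phantom generator: what it emulates and what it does not

`generate_vessel_tree()` grows a branching random walk inside the dermis
band: walkers with direction jitter and per-step radius taper, bifurcating
with a fixed probability, reflected at the band boundaries. A collision
guard terminates a walker before it touches an unrelated branch (clearance
`avoid_um`, default 45 µm ≈ surface gap of several voxels), so the stored
tree is the exact topological ground truth for the skeleton stage; terminal
stubs too short to survive spur pruning (after end retraction) are
discarded at generation time. The stored ground truth dissolves degree-2
nodes — a bifurcation whose second daughter was blocked — so its counts
describe the same graph a topology-preserving skeletonization sees.

`rasterize_tree()` assigns each branch to the low or high band by its mean
radius against a single threshold (default 30 µm). This is an explicit
geometric emulation: in the real device the band split is acoustic
(frequency content), not geometric. An epidermis slab of high intensity is
written above the dermis in both bands; optional Gaussian noise is added
and clipped at zero.

`reactivity_model()` encodes the group effect the clinical literature
reports directionally: radii unchanged at baseline and in occlusion
minute 1, mildly constricted later in occlusion (factor 0.9), dilated at
hyperemia with the healthy factor (1.30 at `hyp1`) above the patient factor
(1.10), plus reserve-branch recruitment with group-dependent probability.
No quantitative clinical effect sizes are available; these defaults are
synthetic study conditions, labelled as such, not estimates of the clinical
effect.

`generate_cohort()` is the feature-level shortcut used for the statistical
stages: baseline features log-normal and identical across groups (so
baseline comparisons are null by construction), follow-up values
`f_t = f_baseline * (1 + phase_t + group * effect + eps)` with
`eps ~ N(0, 0.08)`, and demographics drawn per group (age 64.5 ± 10.5 vs
70.2 ± 9.0 years; BMI 25.3 ± 4.0 vs 26.0 ± 2.7; male 5/13 vs 9/13;
hypertension 4/13 vs 10/13; smoking 0/13 vs 4/13; hyperlipidemia 2/13 per
group; diabetes 0/13 vs 2/13 — the sparse cells exercise the confounding
stage's exclusion rule). The `"strong"` preset shifts nine features
spanning all three scales by two noise standard deviations at `hyp1`.
What passing tests on these phantoms demonstrate is the correctness of the
measurement and inference machinery — not performance on real skin, which
adds speckle, melanin shadowing, motion residuals and anatomy the
generator does not model.

# Statistical choices

* Group comparisons use the classic equal-variance two-sided Student
  t-test (Welch available via `var_equal = FALSE`); boxplot summaries
  report median, quartiles and 1.5-IQR whiskers.
* No multiple-testing correction by default, matching the per-feature
  presentation; Benjamini–Hochberg is available and off.
* Scale aggregation min–max normalizes each feature across the cohort at
  baseline (the normalization per feature; z-scoring would be the obvious
  alternative and is intentionally not the default), then averages
  unweighted within scale; changes are averaged within scale directly.
* Top-k selection ranks features by the one-way between-group F statistic
  computed on training folds only; constant features rank last; ties break
  by feature order. Selection strictly inside each LOSO fold is the
  leakage-free reading of the method and the package default.
* With `k = "auto"`, a full LOSO is run for every k in 1..18 and the k
  maximizing out-of-fold AUC is kept (smallest on ties). This optimizes k
  in-sample over the scan; the per-minute "number of selected features" it
  reports carries that caveat.
* The random forest uses 500 trees, sqrt(p) candidate features per split,
  and a stratified class-balanced bootstrap (equal counts per class per
  tree, 0.8 of the minority class size). The balance matters: leaving one
  subject out makes its class underrepresented 12:13 in training, which
  otherwise biases the held-out probability against the true class and
  pulls the null-data LOSO AUC visibly below 0.5. All forest seeds derive
  deterministically from the user seed.
* AUC is the Mann–Whitney pair form (ties count one half), computed from
  midranks; the confusion matrix uses a fixed 0.5 index threshold by
  default (a Youden-optimal threshold is available and off, since no
  threshold convention is stated for the original analysis).
* The nested confounding models are binomial GLMs with logit link; the
  residual scale of published values (≈30 for n = 26, below the 36.04
  intercept-only bound of 2n·ln 2) identifies "residuals" as logistic
  residual deviance. Added-term p-values use the likelihood-ratio chi-squared
  test (Wald via `wald = TRUE`). The multivariate model is ordinary least
  squares on the 0/1 outcome — a linear probability model, which is what
  coefficient magnitudes near 1 on a probability scale imply — with binary
  confounders excluded when any confounder-by-outcome cell holds fewer than
  3 subjects.

# Problem sizes and degenerate inputs

Phantom volumes default to 600 × 400 × 400 µm at 10 µm isotropic spacing
(60 × 40 × 40 voxels); the statistical calibrations use 13 + 13 subjects
(the case-control size the cohort model mirrors), 10 strong-effect and 100
null cohorts for classification calibration, 500 random datasets for
nested-deviance monotonicity, and about 2000 per-feature baseline tests for
type-I calibration. An empty vessel mask yields an empty graph: count
features are 0 and mean-type features missing. A timepoint whose changes
are all missing or constant is flagged `not_classifiable` rather than
classified. Degenerate two-group comparisons (both groups constant and
equal) return t = 0, p = 1, flagged.

# Known limitations

* The fixed-thickness epidermis band (100 µm) and fixed DE depth (500 µm)
  stand in for signal-based layer-boundary detection; they are exact on
  phantoms and only approximate on real skin with varying epidermal
  thickness. The strategy sits behind `segment_dermis()` and can be
  replaced.
* Depth is measured along z only; strong surface tilt would require
  surface-normal reslicing, which is out of scope at mesoscopy tilt angles.
* Band assignment by geometric radius is an emulation of an acoustic
  phenomenon (see above).
* Exactly corner-symmetric tube cross-sections degrade thinning (shared
  with reference implementations); not reachable from continuous random
  geometry.
* LOSO AUC at n = 26 retains residual finite-sample pessimism of a few
  hundredths under the null even after stratified balancing; the
  calibration band in the tests (mean AUC 0.45–0.55 across 100 null
  cohorts) accounts for it.
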