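---
title: "Linking histological PSMA expression to PET uptake: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking histological PSMA expression to PET uptake: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(histopet)
```

## The problem

Prostate cancer is strongly heterogeneous within a single gland, and the
membrane protein PSMA is overexpressed in proportion to tumour
dedifferentiation. Two measurements of the same biology exist at very
different scales: on digitised whole-mount histological sections a
pathologist outlines PCa areas and an immunohistochemical stain gives each
cell a PSMA staining level; in vivo, PSMA-ligand PET measures tracer uptake
as standardised uptake values (SUV, g/ml) on a 2 mm voxel grid. The question
the package operationalises is whether the PET signal tracks the
*intratumour* variation of histological PSMA expression once both
measurements are brought into the same world frame.

`histopet` implements the full quantification chain: H-Score computation
from cell tables, transfer of 2D section annotations into the 3D PET frame
through a slab model and a supplied transform chain, sub-voxel uptake
extraction, threshold-surrogate gross tumour volumes (GTV) with a Dice-like
agreement statistic, an automated rigid position refinement, and the
nonparametric statistical surface. Because no patient imaging is shipped, a
synthetic phantom generator with complete ground truth provides the test
bed; every stage of the chain is validated against it.

## H-Score

Every cell in an annotated area carries a staining level $i \in \{0,1,2,3\}$
(no to strong expression). The area's H-Score is

$$H = \sum_{i=0}^{3} i \cdot 100\,\frac{n_i}{n} \in [0, 300],$$

computed with exact cell fractions (an AI-assisted classifier produces the
cell table, so there is no reason to round percentages to integers). The
identity $H = 100 \cdot \overline{\text{level}}$ is used as an algebraic
oracle in the tests.

Areas are grouped by expression with closed integer limits
very_low 0–75, low 76–132, medium 133–180, high 181–300. The printed limits
are integers; synthetic data can produce non-integer scores, so each
interval is extended to its half-open real hull $[lo, hi+1)$ (the last is
closed at 300), which keeps assignment total on $[0, 300]$ without moving
any printed boundary. Whether boundaries should instead be half-open at the
printed limits is unknowable from integer limits alone; the choice only
matters for synthetic scores.

When areas are combined, the region's H-Score is the area-weighted mean of
its constituents and the area-weighted SD measures the expression
resolution lost by combining. The SD uses the population (biased) form
$\sqrt{\sum w_i (h_i - \bar h)^2 / \sum w_i}$ — the estimator is a
convention, stated in the output, and a single constituent gives exactly 0.

## From section plane to PET frame

The resected gland is cut into 4 mm slabs aligned to a localizer grid,
numbered from base to apex. Section $s$ occupies the half-open world
interval $[z_0 + (s-1)t,\; z_0 + st)$; half-open intervals make the slabs
partition the gland with no double-counted boundary plane. An annotation
polygon (vertices in section micrometres, even-odd fill so ring 2+ are
holes) is extruded through its slab and mapped by the transform chain —
section→ex-vivo CT (rigid), ex-vivo→in-vivo CT (affine plus an optional
dense displacement field, both *supplied*, never estimated here), in-vivo
CT→PET (rigid) — then rasterised by inverse mapping onto a fine grid at 1/4
of the PET spacing. Rasterisation tests fine-cell centres; volume errors
shrink as the sub-resolution grows and are about 1% at the default.
Displacement fields are inverted by fixed-point iteration, which converges
for the small, smooth deformations the chain is meant to carry.

Two analysis pathways consume the transferred masks:

* **Tumour volumes (pathway 1).** Areas on consecutive sections whose
  transferred masks overlap in-plane are chained into one longitudinal
  lesion (the adjacency rule is a package decision; lesion identity across
  sections is not observable from single sections). Gap slabs between
  occupied sections are filled by shape-based interpolation: the 2D signed
  distance transforms of the bounding in-plane masks are blended linearly
  in z and thresholded at zero. Interpolation runs only *between* occupied
  sections; the alternative reading (extending volumes toward base and
  apex) is deliberately not performed, since nothing outside the annotated
  span is evidence.
* **Tumour areas (pathway 2).** All areas of one patient in the same
  H-Score group are united, with no interpolation along z, so each tumour
  area stays confined to its constituent slabs and carries the weighted
  H-Score mean and SD of its constituents.

## Sub-voxel uptake extraction

Resampling a small region onto the PET grid destroys it, so extraction
never interpolates SUV values. A region is held as fractional occupancy
$w_v \in [0,1]$ per PET voxel (the fraction of the voxel's fine cells
covered), and

$$\mathrm{SUV}_{mean} = \frac{\sum_v w_v \mathrm{SUV}_v}{\sum_v w_v},
\qquad \mathrm{SUV}_{max} = \max\{\mathrm{SUV}_v : w_v > 0\},
\qquad V = \sum_v w_v \cdot v_{vox}.$$

By default any positive overlap makes a voxel eligible for SUVmax
(`max_occupancy_floor = 0`), consistent with protecting small volumes; a
stricter floor is a parameter. Volume is reported fractionally, with the
whole-voxel count alongside. Convergence in the sub-resolution is part of
the test suite (SUVmean moves by well under 0.5% from sub-factor 4 to 16);
single-voxel *weights* converge more slowly because point-sampling
quantises a grazed voxel's weight, which is why tolerances on individual
weights are looser than on the aggregate statistics. For analytic
ellipsoid geometries the eligible support is additionally computed
*exactly* (each voxel box is tested against the ellipsoid by a separable
clamp test), and voxels the region grazes by less than one fine cell enter
with half a fine cell's occupancy: SUVmax eligibility then does not depend
on the sampling resolution. Polygon-derived regions have no closed-form
box test and keep the sampled support.

The surrogate GTV is a fixed SUV threshold with small connected components
(26-connectivity) removed. Manual consensus contouring under display
windows of 0–5 or 0–10 SUV cannot be emulated faithfully; a threshold in
that window range is the closest deterministic stand-in, and it is always
labelled a surrogate. GTV agreement of a tumour area is
$\sum_v w_v \mathbb{1}[v \in \mathrm{GTV}] / \sum_v w_v$ — Dice-like but
normalised by the area only, since the question is how much of the
histological region the PET contour captures. Fractional weights are used
rather than binarised masks, matching the no-resampling philosophy.

## Automated position refinement

The study workflow ends with a small manual correction of each
co-registered region against the PET image (1–16 mm). The automated
surrogate maximises the occupancy-weighted SUVmean over rigid
displacements: a coarse translation grid at the voxel pitch (2 mm) within
±16 mm, then a 0.5 mm refinement around the coarse optimum, decomposing
each sub-voxel shift into an integer-voxel part and a phase so the region
is re-aggregated only once per phase. SUVmean, not SUVmax, is the
objective because the maximum is noise-brittle. Ties are broken toward the
smallest displacement, then lexicographically, which makes the search
deterministic. If the objective is flat in the identity's neighbourhood
(zero-signal PET), the identity is returned with a flag rather than an
arbitrary optimum. A rotation search about the section axis (bounded at
±5°) is implemented but off by default: the misregistrations the procedure
must undo are translation-dominated, and recovery is scored in
translation. Displacements that push the region off the grid lose
objective mass and are thereby penalised.

## Statistics

* **Spearman correlation** with average-rank ties; p-values from the
  standard large-sample t approximation; CIs from a seeded percentile
  bootstrap (default 10,000 resamples) with a Fisher-z option. The
  bootstrap is the default because at the study's sample sizes (tens of
  units) normal-theory intervals for rank correlations are not trustworthy;
  its empirical coverage at n = 76 is checked in the tests.
* **Kruskal–Wallis** via `stats::kruskal.test` (tie-corrected H,
  chi-square df = k−1).
* **Dunn's post-hoc test** from the pooled tie-corrected rank variance;
  implemented in-package (no installed package provides it) and verified
  against an independently coded textbook formula. The default applies *no*
  multiple-testing adjustment — the analysis convention adopted here — with
  Holm and Bonferroni selectable, since the two readings (uncorrected
  p-values vs corrected post-hocs) cannot both be honoured at once.
* **Through-origin regression** $y = \beta x$: $\hat\beta = \sum xy / \sum
  x^2$, SE on n−1 df, and the *uncentered* $R^2 = 1 - \sum r^2 / \sum y^2$,
  because the centred form is ill-defined without an intercept; the
  convention is printed in every output.
* **Cohort comparison of correlations** by the Fisher-z test for
  independent samples — the method is an interpretation (none is forced by
  the analysis design) and is labelled as such.

`run_study()` drives both pathways end to end and emits the per-unit
table, the correlation table over the standard subsets (all units, per
tracer cohort, histological area above 400 µm², patients with GTV over
5 ml, volumes over 1 ml), the group comparisons and the regressions. Every
stochastic step sits behind one master seed.

## The phantom generator

A synthetic patient is an ellipsoidal prostate (default half-axes
20 × 17 × 15 mm) with non-overlapping spherical lesions (default 3, radii
4–12 mm, rejection-sampled with a bounded attempt count), cut into 4 mm
slabs. Each lesion draws per-cell staining levels from its own mixture
over levels 0–3; the default four mixtures give expected H-Scores near 40,
100, 160 and 240 — one per expression group — and 400 cells per area puts
the within-lesion H-Score SD near 4.5, the same order as the small
area-weighted SDs that motivate treating tumour areas as expression-uniform.
A 2-column matrix of radius bands assigns each lesion its own size range,
which the partial-volume experiments use to mix sub-resolution and large
lesions in one patient.

True uptake follows the linear model
$\mathrm{SUV} = b + m \cdot H$ painted per lesion-slab at sub-voxel
fractional occupancy; the defaults $m = 0.09$ g/ml per H-Score unit
(cohort I) and $0.19$ (cohort II) are the calibration scale of the
through-origin fits this package produces, $b = 0.5$ g/ml is a small
physiological background. The scanner is a world-space isotropic Gaussian
PSF (FWHM 4.8 mm, or 4.2 mm for the second tracer's device class,
$\sigma = \mathrm{FWHM} / 2\sqrt{2\ln 2}$, per-axis $\sigma$ in voxel units
for anisotropic grids) followed by i.i.d. additive Gaussian noise (default
SD 0.3 g/ml) clipped at zero. The blur kernel is normalised, so activity
away from the grid boundary is conserved; at the boundary, zero padding
attenuates — phantoms keep a margin so lesions are interior. PET noise is
a controllability knob, not a reconstruction model: the validation needs a
tunable SNR, not scanner physics. GTV truth is the threshold contour on
the noisy blurred volume (5 g/ml cohort I, 10 g/ml cohort II, motivated by
the two display windows). Misregistration injects one rigid transform per
patient with translation magnitude uniform in 1–16 mm (rotation optional,
bounded ±5°, default off so that a degenerate range is exactly the
identity), recorded in the truth block for recovery scoring.

`lesion_shape = "box"` is a calibration geometry: lesions become boxes
snapped to voxel boundaries in-plane and slab boundaries in z, so
rasterisation, painting and extraction are all *exact* and the full chain
(cells → H-Score → polygons → transfer → occupancy → regression) reproduces
the uptake slope to machine precision. With curved lesions, fractional
boundary voxels mix lesion and background activity, biasing SUVmean low by
a few percent for centimetre-scale spheres — a real partial-volume-like
geometry effect, which is why exact-recovery claims are made on the box
geometry and only qualitative claims on spheres.

What the phantom does *not* emulate: anatomically realistic gland and
lesion shapes, deformable ex-vivo shrinkage (the deformable chain step is
applied if supplied, never estimated), scanner reconstruction artefacts,
attenuation and scatter, and intra-lesion expression gradients beyond
section-to-section sampling noise. Passing phantom tests therefore
demonstrates the correctness of the quantification chain under its stated
model, not performance on patient data.

## Validation conditions and problem sizes

The test suite runs the chain at sizes chosen for a single CPU: the
supersampling comparisons use 50 random ellipsoidal regions; slope
recovery uses six box-lesion patients; the partial-volume experiment uses
100 cohorts of 12 patients with three lesion size bands (7–9, 4.2–5.5 and
2.2–3.2 mm radius) and continuous per-lesion expression mixtures, scoring
whether the largest-tertile correlation exceeds the smallest-tertile one;
the group-ordering experiment uses 100 seeds of six 4-lesion patients with
a GTV threshold of 8 g/ml, placed between the blurred uptake of the low
and medium groups so that agreement discriminates the groups; registration
recovery uses 100 single-lesion, high-uptake phantoms with injected 1–16 mm
shifts and a one-voxel (2 mm) success criterion; statistical calibration
uses 10,000 null replicates for the rank tests and 1,000 replicates of
bootstrap interval coverage at n = 76. Experiments that only need rank
orderings run at sub-resolution 2 and paint at sub-factor 2; exactness
claims always run at the default 4.

## Known limitations

* Shape interpolation and slab geometry assume the section normal maps to
  the world z axis; strongly rotating chains would tilt slabs, which the
  interpolation does not model.
* The GTV surrogate is a threshold, not a consensus contour; agreement
  values are comparable within a configuration, not across contouring
  protocols.
* Histological area units are taken as annotated (µm² by convention). The
  size-filter threshold (400 µm²) is a config value applied to whatever
  unit the annotations carry; phantom polygon areas are orders of magnitude
  larger than the clinical medians reported for comparable studies, which
  the package does not attempt to reconcile — the `area_unit` label travels
  with the data.
* Rotation is searched only about the section axis and off by default;
  out-of-plane rotational misregistration is not recovered.
* The bootstrap CI is percentile-based; at very small n (< 10 units) its
  coverage degrades and the Fisher-z option is no better — interpret CIs
  at such sizes with care.
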