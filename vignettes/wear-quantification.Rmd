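---
title: "Quantifying erosive tooth wear from sequential 3D scans: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying erosive tooth wear from sequential 3D scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Erosive tooth wear is monitored by scanning the same tooth at two visits and
measuring how much hard tissue was lost in between. The computation has three
stages, and each can corrupt the answer:

1. **Rigid alignment.** The two scans arrive in arbitrary poses. They are
   registered on *reference surfaces* — the buccal (cheek-side) and lingual
   (tongue-side) walls, assumed unchanged — so that change on the measured
   occlusal (biting) surface is not minimised away by the very algorithm that
   aligns the scans.
2. **Distance measurement.** With the scans in a common frame, signed
   distances from the baseline occlusal surface to the follow-up surface are
   taken *perpendicular to the occlusal surface* (a single plane normal, not
   per-vertex normals). Negative distances are material loss.
3. **Aggregation and statistics.** Per-surface outcomes (volume change in
   mm³, maximum point loss and mean profile loss in µm) feed a paired
   nonparametric analysis.

`wearbench` implements two alignment strategies that are used in practice and
behave very differently when the assumptions are violated:

* **`bestfit`** — unconstrained two-stage ICP in the style of engineering
  inspection software: the occlusal region is deleted from both scans, an
  untrimmed ICP runs on 1000 sampled reference points and is refined with
  5000 points, and the composed transform is applied to the complete
  follow-up scan. There is **no outlier rejection**: every correspondence on
  the reference surfaces votes, including ones where the reference itself
  changed.
* **`feature_trimmed`** — a feature-based coarse global alignment on the
  full scans (curvature keypoints, multi-scale normal-deviation descriptors,
  RANSAC), followed by a trimmed ICP on the reference surfaces in which only
  corresponding points **within 25 µm** of each other are kept, re-evaluated
  every iteration.

The operative difference under study is exactly trimming/feature
initialisation versus none; everything else (sampling, metric, convergence)
is shared.

## Registration details

ICP alternates closest-point correspondence, optional trimming, and a rigid
solve. Two solvers are provided:

* `point_to_point`: closed-form SVD (Kabsch), reflection-corrected; its
  objective is monotone non-increasing when untrimmed. It converges slowly
  along directions in which surfaces can slide tangentially.
* `point_to_plane` (default): one linearised Gauss–Newton step against the
  face normals at the closest points, re-orthonormalised through an SVD
  polar projection. This is the standard choice for smooth surfaces and is
  what the convergence claims in the test-suite are made for.

Convergence is declared when the inlier RMS improves by less than 0.1 µm
(well below the 2.6 µm scanner noise floor) or after 100 iterations.
Closest-point and ray queries run on a bounding-volume hierarchy and are
bitwise-identical to brute force; ties are broken by the lowest face index so
every run is deterministic.

Two bridging choices were genuinely open and are package decisions:

* The published trimmed-ICP protocol jumps from a coarse feature alignment
  (residual ~0.1–0.2 mm) straight to a 25 µm band, which would leave no
  inliers. A brief **untrimmed warm-up stage** (1000 points) is inserted
  between the feature alignment and the trimmed refinement. Fewer than 3
  inliers at 25 µm raises a degenerate-alignment error rather than silently
  proceeding.
* The best-fit strategy's initialisation is unspecified in the protocols it
  mimics; principal axes + centroid of the reference submeshes is used
  (deterministic, documented, adequate for pose offsets up to tens of
  degrees).

## Wear metrics

For every baseline occlusal vertex a bidirectional ray is cast along the
occlusal-plane normal into the follow-up surface. Misses are flagged invalid
and excluded from every aggregate — silent imputation is exactly the error
mode this pipeline is designed to expose — and a valid fraction below 50%
is an error.

* **Volume change** = Σ dᵢ·Aᵢ over valid vertices, in mm³, negative for
  loss. Aᵢ is the one-third barycentric vertex area of the baseline occlusal
  submesh **projected along the measurement direction**. Projected (not raw
  3D) areas make the rectangle rule exact for height-field wear; raw areas
  would inflate volumes by the surface slope factor (several percent on a
  cusped crown). The unprojected areas are also carried in the distance map.
* **Maximum point loss** = |most negative dᵢ| in µm. It is deliberately a
  pointwise extreme and therefore outlier-sensitive; a single noisy vertex
  moves it.
* **Mean profile loss** averages |dᵢ| over **loss vertices only** (dᵢ < 0),
  area-weighted. Published profile-loss values far exceed what a full-surface
  average of the corresponding volumes would give, implying a loss-restricted
  average; an all-vertex variant is available via `loss_only = FALSE`.
* **Truncation** ("positives set to zero") is applied at the per-surface
  level: a positive surface total becomes 0, negative totals are unchanged.
  This is the variant whose summary tables show IQR upper bounds clamped at
  0.00 with unchanged medians for all-negative groups. A per-vertex variant
  (`truncate_map_positive()`) is exposed for sensitivity analysis.

## The synthetic world

No clinical scans ship with the package; instead a generator produces
baseline/follow-up pairs with exact ground truth.

**Crown.** A molar-like shell in canonical pose: a domed top with four
Gaussian cusps (occlusal label inside a 3.5 mm footprint radius for the
default 10 mm crown), tapering side walls with a mild mid-height bulge on the
two opposite sides — which produces genuine undercuts — and a base ring.
Seeded cusp jitter plus a low-frequency ~25 µm surface ripple makes each
crown individual; that individuality is what the feature descriptors key on.

**Wear.** Occlusal wear is a depth field along the occlusal-plane normal
(Gaussian lesions: volume 2πaσ² exactly; spherical caps: πh²(3r−h)/3), so
the ground-truth volume is analytic, not numerical. The follow-up can also
carry shallow **smooth-surface wear on the reference walls**
(`apply_reference_wear()`, cohort default: each side with probability 0.7, a
1 mm Gaussian patch of log-normal peak depth, median 35 µm, in the occlusal
third of the wall). Changed reference surfaces are the clinically documented
failure mode of unconstrained best-fit alignment; a world whose reference
surfaces are bitwise identical between visits cannot express the contrast the
factorial experiment exists to study. The ideal-capture limit test disables
reference wear together with noise and pose offset, because it is one of the
hypothesised causes of the factorial effect.

**Profilometer capture.** The top-most surface height is sampled on a 50 µm
raster (step-over) with i.i.d. Gaussian height noise of SD 2.6 µm
(instrument repeatability). Because a raster grid stores one z per (x, y),
undercuts are invisible by construction; grid nodes whose vertical line
misses the object become missing cells and are dropped, never interpolated.

**Intraoral capture.** A vertex-clustering remesh to ~0.2 mm (4× coarser
than the profilometer raster, encoding "lower-resolution"), uniform-weight
Laplacian smoothing (10 iterations, λ = 0.5 — the generic
interpolation/averaging that smooths topography), and 10 µm isotropic vertex
noise. Undercuts are retained. No vendor's stitching algorithm is modelled.
The cluster grid lives in the scan's own principal-axes frame: a
world-aligned grid would make the capture artifact depend on the arbitrary
pose the scan arrived in, which injected a systematic pose-coupled vertical
settle (~10 µm) into every alignment strategy — an artifact of the grid
implementation, not of the scanner being modelled. A handheld scanner's
artifacts travel with the object.

**Cohort.** Per surface: an individual crown, 2–3 occlusal lesions with
log-normal amplitudes (median peak depth 0.25 mm, widths ~0.5 mm, giving
per-surface true volumes of order 1 mm³ — the order of magnitude of
published 3-year clinical wear), optional reference wear, and a random pose
offset ≤ 5°, ≤ 2 mm between visits. Everything is a pure function of the
master seed.

What a green test does **not** establish: the generator has no saliva or
scan-spray artifacts, no operator variability, no restorative materials, no
multi-tooth arches, and its lesion distribution is a stated default rather
than an estimate of any clinical cohort. Directional findings (which
strategy is more biased, and which way) transfer; magnitudes do not.

## Statistics

* `wilcoxon_signed_rank()`: midranks for ties, statistic W = min(W⁺, W⁻).
  For n ≤ 25 without ties the two-sided p is exact — the fraction of the 2ⁿ
  sign assignments with min(W⁺, W⁻) ≤ the observed value, computed by shift
  convolution (identical to enumeration). This differs slightly from the
  `2·min(tail)` convention of some software; the enumeration definition is
  the one the package's oracle tests check. Otherwise a normal approximation
  with continuity and tie correction is used. Zeros are dropped by default
  (classical Wilcoxon policy); Pratt's method is an option.
* `icc_single()` is ICC(A,1) — two-way, absolute agreement, single measures
  — with the standard F-based confidence interval. Absolute agreement is
  chosen because the scientific question is whether two measurement methods
  agree, not merely co-vary. The model choice is stated in the output.
* `bonferroni_alpha(0.05, 6)` = 0.00833…, printed as .008 at the reporting
  layer. The default family of 6 is the scanner contrast within each of the
  two strategies for each of the three metrics; the family is declared
  explicitly in `factorial_config()` and m is simply its length, so a
  different family is a configuration change, not a code change.
* `sample_size_for_correlation()` inverts a power function built from the
  bias-corrected Fisher z distribution of the sample correlation (mean
  atanh ρ + ρ/(2(n−1)), SD 1/√(n−3)) against the t-based critical r. For
  ρ = 0.4, α = .05, power .95 it returns 75 pairs; tests cross-check the
  analytic power against Monte Carlo.
* Quartiles use linear interpolation (type 7); stated because IQR bounds
  differ across conventions.

## Numerical choices and degenerate inputs

* Units: mm everywhere internally; µm/mm³ only at the reporting layer.
* STL welding tolerance 1e-9 mm; PLY (ascii or binary little-endian) is the
  canonical format and carries labels losslessly as a `uchar` vertex
  property.
* A face belongs to a region iff all three vertices carry the label;
  submesh extraction is therefore unambiguous, at the cost of a one-face
  boundary strip.
* Degenerate (zero-area) faces are dropped at construction; collinear input
  to the plane fit, empty submeshes, all-zero difference vectors, and
  fewer than 3 ICP inliers are errors, not warnings.
* All randomness is seeded and scoped (`with_preserved_seed`), so library
  calls never disturb the caller's RNG stream and every pipeline output is
  reproducible bitwise on one platform.

## Known limitations

* Point-to-point ICP converges slowly along tangential directions and may
  stall ~1° from the optimum on smooth wall geometry; point-to-plane is the
  default for this reason.
* The feature matcher needs distinctive curvature structure. On nearly
  featureless shapes (a sphere, heavily smoothed captures) it falls back to
  principal axes + centroid with a warning; the warm-up ICP stage absorbs
  the coarser start.
* The intraoral remesh can introduce isolated non-manifold contacts
  (vertex clustering); all downstream consumers (sampling, BVH queries,
  smoothing) are robust to this, but `validate_scan(manifold = TRUE)` is
  only guaranteed for generator and raster meshes.
* Single-tooth analysis only; cropping/labelling of the tooth surface is
  treated as given input.
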