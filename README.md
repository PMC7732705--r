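# wearbench

Quantifies erosive tooth wear between sequential 3D scans of a tooth crown,
and stress-tests the two rigid-alignment philosophies used in dental wear
research against each other on synthetic data with exact ground truth.

## Who this is for

Dental researchers and metrologists who measure hard-tissue loss from
longitudinal scan pairs (laboratory profilometry of study models, or
intraoral scans), and who need to know how much of a reported "volume
change" is biology and how much is pipeline artifact. No clinical data ship
with the package: a synthetic crown generator provides baseline/follow-up
pairs whose true wear volume and true pose offset are known analytically, so
every stage — alignment, distance measurement, statistics — is testable.

## What it computes

Given a baseline scan and a follow-up scan of the same tooth (PLY/STL/OBJ
triangle meshes with per-vertex region labels, or raster height grids):

1. **Alignment** on the buccal/lingual reference surfaces (assumed
   unchanged), by either strategy under study:
   - `bestfit` — unconstrained two-stage ICP (1000 then 5000 sampled
     points, no outlier rejection), in the style of engineering inspection
     software;
   - `feature_trimmed` — feature-based coarse alignment (curvature
     keypoints + descriptors + RANSAC), then trimmed ICP keeping only
     corresponding reference areas within 25 µm of each other.
2. **Wear metrics**, measured perpendicular to the occlusal surface: for
   per-vertex signed distances d_i (µm, negative = loss) and projected
   vertex areas A_i (mm²),

   - volume change = Σ d_i·A_i (mm³, loss negative),
   - maximum point loss = |min d_i| (µm),
   - mean profile loss = area-weighted mean |d_i| over loss vertices (µm),
   - truncated volume: positive per-surface totals set to zero
     (the "gain is error" secondary analysis).
3. **Statistics**: median (IQR) summaries, paired Wilcoxon signed-rank tests
   (exact by enumeration for n ≤ 25 without ties, statistic W = min(W⁺,W⁻))
   with Bonferroni correction (.05/6 → .008), single-measures ICC(A,1) with
   F-based 95% CI, and an a-priori power analysis for detecting a
   correlation (ρ = 0.4, α = .05, power .95 → n = 75 pairs).
4. **The factorial experiment**: `run_factorial()` crosses capture model
   (profilometer: 50 µm raster, 2.6 µm noise, blind to undercuts; intraoral:
   ~0.2 mm remesh + Laplacian smoothing + noise, sees undercuts) with the
   two alignment strategies on a seeded synthetic cohort, and audits every
   cell against ground truth (bias, RMSE, fraction of physiologically
   impossible positive volumes).

## Worked example

```r
library(wearbench)

# a synthetic molar with a known occlusal lesion (volume 2*pi*a*sigma^2)
crown  <- generate_crown(seed = 42)
lesion <- lesion_config(lesion_gaussian(center = c(0.5, -0.3),
                                        amplitude_mm = 0.4, sigma_mm = 0.8))
worn <- apply_wear(crown, lesion)
worn$true_volume_mm3
#> [1] 1.608495

# the follow-up arrives in an unknown pose and is captured intraorally
moved    <- perturb_pose(worn$scan, max_angle_deg = 5,
                         max_translation_mm = 2, seed = 7)
baseline <- simulate_intraoral(crown, scanner_config("intraoral", seed = 1))
followup <- simulate_intraoral(moved$scan, scanner_config("intraoral", seed = 2))

for (strategy in c("bestfit", "feature_trimmed")) {
  al <- align_pair(baseline, followup, strategy)
  print(measure_wear(baseline, al$aligned, surface_id = "demo",
                     scanner = "intraoral", software_strategy = strategy))
}
#> wear_result [demo intraoral bestfit]: volume -1.734 mm^3, max loss 354.7 um, mean loss 61.2 um (100% valid)
#> wear_result [demo intraoral feature_trimmed]: volume -1.764 mm^3, max loss 355.6 um, mean loss 61.1 um (100% valid)
```

Reading the output: the true removed volume is 1.608 mm³, so both
strategies are within ~10% here; the intraoral capture's smoothing has
shaved the 400 µm deep lesion peak to ~355 µm of detectable point loss.
On a full cohort with realistic smooth-surface wear on the reference walls,
the unconstrained `bestfit` cell drifts toward spurious gain relative to
`feature_trimmed` — the directional effect the factorial experiment (and the
acceptance suite) checks.

A whole study in one call:

```r
res <- run_factorial(factorial_config(n_surfaces = 30, seed = 1))
res$audit            # per-cell volume bias / RMSE vs ground truth
cat(render_report(res), sep = "\n")
```

A command-line front end covering simulate / align / measure / run lives in
`inst/scripts/wearbench`.

## Layout

- `R/`, `src/` — mesh core (+Rcpp BVH), I/O, synthetic generator,
  registration, wear metrics, stats, experiment orchestration, CLI.
- `vignettes/wear-quantification.Rmd` — the methods vignette: models,
  parameters, numerical choices, what the synthetic world does and does not
  establish.
- `tests/testthat/` — unit, property and acceptance suites with
  independent brute-force/enumeration oracles in `helper-oracles.R`.
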