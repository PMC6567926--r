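---
title: "Quantifying lung airspaces in high-resolution CT slices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying lung airspaces in high-resolution CT slices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(airspacer)
```

## The problem

At a voxel size of 47.7 um, synchrotron-grade CT resolves the gas-filled
units of lung parenchyma — "airspaces", bounded by tissue-density septa —
without resolving individual alveolar walls (inter-alveolar septa are
thinner than one voxel, and in the rabbit most alveoli open directly onto
alveolar ducts, so the resolvable unit is the duct-plus-alveoli complex).
Two competing descriptions of lung deflation make different predictions
about what such images should show as airway pressure falls:

* **derecruitment** ("digital" deflation): airspaces close abruptly when
  pressure drops below their individual critical closing pressure, so the
  *number* of airspaces falls while the open ones keep their size;
* **isotropic** ("analog") deflation: all airspaces stay open and shrink
  together, so the number is constant and the *size* falls.

The package quantifies both signatures from slice stacks. Two metrics
carry the analysis:

* **ASden**, airspace density: detected airspaces per mm^3 of analysed
  region;
* **ASext**, average airspace surface extension: the total pixel area
  covered by airspaces divided by the total count, summed over all
  analysed slices (a ratio of sums, *not* a mean of per-slice ratios —
  the two differ whenever counts vary across slices), expressed in
  voxels of slice area.

Each slice is partitioned into three concentric regions of interest by
depth from the pleural surface — subpleural (0–2 mm), mantellar
(2–4 mm), core (>= 4 mm) — because superficial and deep parenchyma are
subject to different local traction forces and may deflate differently.

## Detection chain

Airspaces are dark (negative intensity peaks) against bright septa, so
the detector works with **black top-hat transforms**: morphological
closing with a flat disk minus the image. A feature responds when it is
smaller than the structuring element. Because airspaces span a size
range — alveolar scale (~110 um, 2.3 px) up to duct scale (0.5–0.75 mm,
~16 px) — a *sequence* of top-hats with increasing disk radii (default
1, 2, 3, 5, 8, 12, 16 px) is applied, each response binarized into its
own map, and the binary maps superimposed by pixel-wise union. The
union is the gas-candidate map. The binarization threshold is shared
across the scale sequence and derived (Otsu on a 256-bin histogram over
`[0, max]` by default) from the pixel-wise *maximum* response over all
scales: a top-hat residue of a detected feature equals the feature's
depth at every sufficient scale, while a small-element response on
noisy data may contain no true feature at all — thresholding such a
response in isolation would split pure noise and flood the candidate
map. The rule keeps the chain invariant to positive affine rescaling of
the intensities.

Counting then finds **regional minima** of the grayscale slice
restricted to the candidate map (within the lung mask, outside the
exclusion mask): a connected plateau of equal-valued pixels strictly
darker than every neighbour counts as exactly one peak. Candidate
components with several peaks are split by nearest-peak assignment;
components with no peak, or smaller than `min_area_vox` (default 2 px),
are dropped. One label per airspace, with its pixel area, results.

Two numerical choices matter here:

* `smooth_sigma_px` (default 1 px): a separable Gaussian applied to the
  slice before minima detection. The interior of a rendered airspace is
  flat, so without smoothing any amount of noise creates several strict
  local minima per airspace and the count is biased upward; smoothing at
  the scale of the smallest airspaces turns each one into a single
  basin. Set it to 0 for strictly noiseless data.
* ties and determinism: plateau minima are merged by construction;
  labels, peak representatives and split assignments are all resolved in
  column-major scan order, so results are bit-reproducible.

The depth map is an exact Euclidean distance transform of the lung mask
(per-slice, 2D — the slices lie on iso-gravitational planes and are
analysed independently); the ROI intervals are half-open, so a pixel at
exactly 2 mm is mantellar. Each airspace belongs entirely to the ROI
containing its peak pixel: counts stay integral and per-ROI counts sum
exactly to the slice count. The ROI volume is the per-ROI pixel count
summed over the analysed slices times the voxel volume
(0.0477^3 mm^3) — only the analysed slices enter, never the whole lung.

## Phantom generator

No public raw data accompany this class of acquisitions, so the package
ships a first-class synthetic phantom: an elliptical parenchyma mask
with a circular "pericardiac" exclusion notch, populated with
non-overlapping dark disks (dart-throwing placement with minimum
centre distance `r_i + r_j + septum`, guaranteeing resolvable septa and
hence unambiguous ground truth; an unplaceable request errors with the
achievable maximum). Each airspace draws a radius from a truncated
Gaussian and a critical closing pressure from a Gaussian (a uniform
option exists, reflecting the unresolved shape of that distribution in
the literature). A pressure series reuses one population across all
steps, so deflation is a property of the population rather than of
resampling.

Defaults, chosen once as the study conditions and not revisited:

| parameter | default | rationale |
|---|---|---|
| slices per stack | 40 | conventional acquisition depth |
| voxel side | 47.7 um | acquisition resolution |
| image | 256 x 256 px | smallest frame whose mask reaches > 4 mm depth, so all three ROIs are populated |
| airspaces/slice | 400 | reliably placeable under the separation rule (dart throwing saturates near ~450 for this geometry) |
| radius | N(110, 15) um, min 80 | alveolar scale; gives mean airspace area ~ 17 voxels |
| septum | 50 um (~1 px) | resolvable walls |
| closing pressure | N(-8, 5) cmH2O | ~5% of airspaces close between 12 and 0 cmH2O, the magnitude of density decline reported in vivo for healthy lungs |
| size-pressure slope | 0.01 /cmH2O | isotropic mode: ~25% area change over the protocol range |
| gas / tissue gray | 0.2 / 0.8 | dark gas, bright septa |
| noise SD | 0.02 | ~3% of contrast |

What the phantom deliberately does **not** emulate: radiographic physics
(beam hardening, scatter, ring artifacts), 3D airspace connectivity
across slices (slices are i.i.d. repeats of a 2D process), airway-tree
avalanche dynamics, and realistic packing density. The last point is a
real limitation: non-overlapping disks with resolvable septa saturate
near ~100–120 airspaces/mm^3, roughly half the density measured in vivo,
where airspaces tile the parenchyma. Passing tests therefore demonstrate
correctness of the measurement chain on resolvable, well-separated
airspaces — not detector performance on real, contiguous parenchyma.
ASext magnitudes, by contrast, land in the observed 16–18 voxel range by
construction of the radius distribution.

The simulated experiment (`simulate_experiment()`) runs 7 animals
through the decremental protocol (nominal PEEP 12, 9, 6, 3, 0 cmH2O).
Measured PEEP is drawn per animal around typical step means
(12.3 ± 0.5 down to 1.2 ± 0.4 cmH2O) and drives the phantom physics;
regressions default to the measured values as regressor.

## Statistical layer

Per ROI and metric, an ordinary least-squares regression of the metric
on PEEP is fitted, conventionally with one observation per animal per
pressure (the 40 slices are already aggregated by the metrics; in a
balanced design this choice leaves the slope identical to a fit on
per-pressure means — an identity the tests verify to 1e-10).
Two regressions are compared by the extra-sum-of-squares F-test, by
default the 2-dof coincidence form (common line vs separate lines), with
a 1-dof slopes-only variant. Differences between ROIs at a given
pressure use the paired Wilcoxon signed-rank test: zero differences are
dropped, and for up to 15 effective pairs the two-sided p-value is exact
by enumeration of all sign assignments — valid under ties, where the
classical signed-rank distribution is not — otherwise a tie-corrected
normal approximation is used. Families of comparisons use a Bonferroni
corrected alpha (0.05/n; Holm's sequential procedure is available).

One worked identity is worth stating: the OLS slope of a reference in-vivo
mean density profile {233.5, 230.6, 229.1, 224.7, 216.7} on the nominal
steps {12, 9, 6, 3, 0} is Sxy/Sxx = 118.5/90 = 1.3167. A fit to
disaggregated per-animal data generally differs from the fit to its
group means unless the design is balanced, so this value is a
correctness anchor for the regression code, not a reproduction of any
disaggregated per-animal fit.

## Design choices on open points

* **2D per-slice analysis** throughout (counting, depth): the metrics
  are defined by per-slice sums, and slices sit on iso-gravitational
  planes; no 3D linking is attempted.
* **Peak-based ROI assignment** (not centroid or area-weighted
  splitting): keeps counts integral and conservative. An airspace
  straddling the 2 mm line with its peak at 1.5 mm is entirely
  subpleural.
* **Touching airspaces are split** by nearest-peak assignment; whether
  the original MATLAB chain split them is unknowable, so this is a
  documented deviation risk of one-to-one comparisons.
* **Surface accounting** includes only pixels of retained (labelled)
  airspaces; components removed by the area filter contribute neither
  count nor surface.
* **Phase retrieval is optional and off by default**: phantoms emulate
  already-reconstructed slices. The single-distance filter
  (`paganin_filter()`) exists for users starting from propagation-based
  intensity data; its distance and delta/beta defaults are placeholders
  that must be set from the acquisition geometry. FFT (periodic)
  boundary handling is used.
* **ASext of an empty ROI is missing**, not zero (the ratio is
  undefined), and missing cells are excluded from regressions and
  reported as NA.

## Problem sizes used in validation

The shipped tests validate morphology, depth and partition against
brute-force oracles on exhaustive <= 32 x 32 fixtures; count recovery on
a 40-slice, 600-airspace phantom with septa and radii >= 2 px (exact
recovery without noise, <= 5% error at noise equal to 10% of the
gas-tissue contrast); and the full mechanism contrast on 7 simulated
animals x 5 pressures x 40 slices of 256 x 256 px in both deflation
modes. These sizes are the package's validation conditions; larger
stacks run identically.

## Known limitations

* Counting accuracy is demonstrated for airspaces separated by
  resolvable septa; real parenchyma at this resolution contains walls
  below one voxel, where detected counts are systematically
  resolution-limited.
* The phantom's airspace density is below in-vivo values (see above).
* No anatomical discrimination between alveoli and ducts is attempted —
  the resolvable unit is deliberately called an "airspace".
* Depth, and hence the ROI partition, is 2D per slice; a 3D pleural
  surface would shift depths near strongly curved regions.
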