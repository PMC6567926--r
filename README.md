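# airspacer

Quantification of gas-filled airspaces in high-resolution (synchrotron-grade)
lung CT slice stacks, with the statistical layer needed to characterize how
the lung deflates during a decremental PEEP (positive end-expiratory
pressure) trial, and a ground-truthed phantom generator that makes the whole
chain testable without raw imaging data.

## Who this is for

Researchers analysing phase-contrast CT (or comparable ~50 um resolution)
images of lung parenchyma who want to measure, per concentric region of the
lung and per pressure step:

- **ASden** — airspace density, detected airspaces per mm^3 of analysed
  region;
- **ASext** — average airspace surface extension (voxels),

      ASext = ( sum_k surface covered by airspaces in slice k )
              / ( sum_k number of airspaces in slice k )

  a ratio of sums over the analysed slices, *not* a mean of per-slice
  ratios.

The scientific question behind the two metrics: when airway pressure falls,
does the lung lose *airspaces* (derecruitment — airspaces close when
pressure drops below their individual critical closing pressure) or does it
lose *airspace size* (isotropic shrinkage)? A falling ASden with stable
ASext is the signature of derecruitment; the reverse pattern is the
signature of isotropic deflation.

## The method

1. **Detection** (`detect_stack()`): a sequence of black top-hat transforms
   (morphological closing minus image) with disk structuring elements of
   increasing radius (default 1–16 px, spanning alveolar to duct scale);
   each response binarized against a threshold shared across scales (Otsu
   on the maximum response, by default); binary maps
   superimposed by union; airspaces counted as regional minima (connected
   equal-valued plateaus strictly darker than all neighbours count once) of
   the slice restricted to the candidate map, with multi-peak components
   split by nearest peak.
2. **Concentric ROIs** (`boundary_depth()`, `partition_rois()`): exact
   Euclidean depth from the pleural boundary partitions each slice into
   subpleural (0–2 mm), mantellar (2–4 mm) and core (>= 4 mm); an exclusion
   mask (e.g. the pericardiac region) overrides. Each airspace belongs to
   the ROI holding its peak pixel.
3. **Metrics** (`roi_metrics()`, `compute_asden()`, `compute_asext()`).
4. **Statistics** (`fit_peep_regression()`, `compare_regressions()`,
   `wilcoxon_paired()`, `summarize_run()`): OLS of each metric on PEEP per
   ROI, extra-sum-of-squares F-tests between ROI regressions, exact paired
   Wilcoxon signed-rank tests (enumeration up to n = 15, valid under ties),
   Bonferroni/Holm multiplicity handling.
5. **Phantoms** (`phantom_spec()`, `generate_phantom()`,
   `pressure_series()`, `simulate_experiment()`): stochastic
   critical-closing-pressure populations rendered as dark disks with
   resolvable septa, with full ground truth, in derecruitment, isotropic or
   mixed deflation modes.

An optional single-distance phase-retrieval filter (`paganin_filter()`) is
provided for users starting from propagation-based intensity images.

## Worked example

```r
library(airspacer)

spec <- phantom_spec(seed = 11)            # 40 slices, 256x256, 47.7 um
phantom <- generate_phantom(spec, pressure = 12)
detection <- detect_stack(phantom$stack,
                          masks = phantom$truth$lung_mask,
                          exclusions = phantom$truth$exclusion_mask)
detection
#> <airspace_map> 40 slice(s), 16000 airspaces, 274916 surface px

roi_metrics(detection, phantom$truth$partition,
            pressure_nominal = 12, pressure_measured = 12.3)
#> # A tibble: 4 x 9
#>   animal pressure_nominal pressure_measured roi        count surface_vox
#> 1 <NA>                 12              12.3 ALL        16000      274916
#> 2 <NA>                 12              12.3 subpleural  9035      155352
#> 3 <NA>                 12              12.3 mantellar   5731       98104
#> 4 <NA>                 12              12.3 core        1234       21460
#>   volume_mm3 asden asext
#> 1      174.   91.7  17.2
#> 2      102.   88.8  17.2
#> 3       59.6  96.2  17.1
#> 4       13.1  94.2  17.4
```

The 16,000 detected airspaces equal the phantom's ground-truth open count
exactly (this phantom is near-noiseless and all septa are resolvable); mean
airspace surface is ~17 voxels, i.e. ~39,000 um^2 at 47.7 um voxels; the
density of ~90–96 /mm^3 reflects the phantom's packing limit (see the
methods vignette).

A full simulated study and report:

```r
metrics <- simulate_experiment(n_animals = 7, seed = 42)
report  <- summarize_run(metrics)          # regressions, F-tests, Wilcoxon
report$regressions                          # per-ROI slopes of ASden/ASext
plot_roi_metrics(metrics)                   # ggplot: metric vs PEEP by ROI
```

Under the default derecruitment phantom, ASden rises significantly with
PEEP in every ROI (slopes ~0.24 /mm^3 per cmH2O, p < 1e-3) while the ASext
slope confidence intervals contain 0; switching
`phantom_spec(deflation_mode = "isotropic")` reverses the pattern.

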