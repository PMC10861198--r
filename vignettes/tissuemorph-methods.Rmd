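---
title: "Methods: quantifying implanted-cell phenotypes in tissue sections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying implanted-cell phenotypes in tissue sections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and model

`tissuemorph` quantifies how an implanted cell population behaves inside a
tissue section imaged by multi-channel fluorescence microscopy. The
scientific question it serves is a comparison between two cell states —
e.g. aged fibroblasts versus mechanically partially-reprogrammed (PR)
fibroblasts implanted into a skin model — along five readouts:

1. **Nuclear morphometrics.** Nuclei are segmented from the nuclear-stain
   channel and described by a fixed catalog of 24 features in four groups
   (chromatin texture, nuclear morphology, global intensity profile,
   nuclear boundary).
2. **Cell-state score.** A two-class linear discriminant trained on those
   features yields a per-nucleus LDA1 projection, min-max normalized to
   [0, 1].
3. **Spreading.** The internuclear pairwise-distance (IPD) matrix
   `IPD[i,j] = sqrt((x_i - x_j)^2 + (y_i - y_j)^2)` in micrometres, and its
   dispersion (sample SD over unique pairs), measure how widely the
   implanted cells distribute.
4. **Local organisation.** Epsilon-free hierarchical density-based
   clustering (HDBSCAN-style) groups nuclei by position plus score; each
   cluster reports its mean score and the mean pairwise axial angular
   difference of nuclear long axes.
5. **Matrix remodeling.** A structure-tensor orientation field of the ECM
   (collagen) channel gives per-pixel fiber direction, coherency and
   energy; the axial circular width of the orientation histogram measures
   fiber alignment. ROI intensity fold changes and 2^-ddCt qPCR fold
   changes quantify protein/mRNA levels.

All coordinates are Cartesian micrometres with the origin at the image's
lower-left corner (x rightward, y upward; image row 1 is the top row);
orientations are axial angles in degrees, counterclockwise from +x,
wrapped to (-90, 90]. This convention is applied uniformly to nuclear long
axes and fiber directions so that angular statistics are comparable across
modules.

# The synthetic-data generator: what a green test establishes

No imaging data ship with the package; every stage is validated against a
generator with known ground truth.

* **Nuclei** are textured ellipses: area lognormal with requested mean and
  CV; aspect ratio with requested mean; long-axis orientation from an
  axial wrapped-normal; boundary radius perturbed by a random low-order
  (2-5) Fourier series with relative amplitude `boundary_irregularity`;
  intensity `base * (1 + texture_contrast * t)` where `t` is unit-variance
  band-passed Gaussian noise at the chromatin granularity scale. The scene
  adds a constant background and Gaussian read noise at SNR 10 by default
  (SNR = (foreground - background) / noise SD), matching a clean confocal
  acquisition.
* **Placement** draws candidate centres from an isotropic Gaussian of SD
  `dispersion` about the image centre and rejects out-of-bounds or
  overlapping candidates, with a retry budget of 100 per nucleus. Because
  the candidate stream is fixed per seed, rescaling `dispersion` rescales
  all accepted centres exactly whenever no candidate is rejected — which
  is what makes the dispersion-doubling tests exact rather than
  statistical.
* **Fiber images** superpose straight line segments whose axial angles
  follow a wrapped-normal on the doubled-angle circle. The
  `concentration` parameter is the reciprocal of the axial angular SD in
  radians (`concentration = 0` means uniform). We deliberately did not use
  a von Mises kappa: a kappa of 100 still leaves an axial SD of ~3
  degrees, while the generator's contract (high concentration pins ~all
  segments within 2 degrees of the mean) requires the reciprocal-SD
  reading.

The generator emulates two-population contrast, spatial dispersion and
axial fiber order. It does **not** emulate optical point-spread functions,
photobleaching, 3-D sectioning artifacts, epidermal autofluorescence
layers, or touching/overlapping nuclei. A green test therefore establishes
algorithmic correctness on idealized tissue, not robustness to every
acquisition pathology.

# Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `pixel_size` | 0.5 | um/px | matches 20-40x confocal sampling |
| `local_block` (segmentation) | 64 | px | local Otsu block; intersected with the global Otsu threshold |
| `min_area`, `max_area` | 10, 400 | um^2 | artifact filter; large dim autofluorescent regions are removed by size and `min_mean_intensity` |
| `sigma` (structure tensor) | 2 | um | Gaussian tensor-window scale; logged in every run config |
| `min_cluster_size` | 5 | nuclei | smallest density cluster |
| `train_fraction` | 0.75 | – | LDA train/test split |
| `shrinkage` | auto = p/(p+n) | – | pooled-covariance shrinkage toward its diagonal |

# Numerical choices

* **Segmentation** intersects the global Otsu threshold with block-wise
  local Otsu thresholds (a pixel must pass both): the conservative reading
  of "local and global" that suppresses dim autofluorescence. Components
  use 8-connectivity; holes are filled before measurement; touching nuclei
  merge (no watershed: a documented limitation). A constant image returns
  zero records with a warning rather than an error.
* **Gradients** for the structure tensor use separable Gaussian-derivative
  filters at 1 px scale. Plain centered differences carry a ~1.3-degree
  orientation bias on discrete gratings; Gaussian derivatives recover
  gratings at any angle to < 0.01 degree. The reported angle is the fiber
  (isophote) direction, i.e. gradient direction + 90 degrees.
* **Coherency** is `(l_max - l_min)/(l_max + l_min)` of the smoothed
  tensor, defined as 0 where the trace vanishes; energies below a
  relative tolerance of the image range are clamped to exactly zero so a
  constant image reports identically zero energy.
* **Axial width** is the circular SD of doubled angles,
  `(90/pi) * sqrt(-2 log Rbar)`, capped at the uniform-limit value
  `(90/pi) * sqrt(2) = 40.514` degrees (the cap corresponds to
  `Rbar = e^-1`; beyond it the statistic is no longer informative and
  uniform data would otherwise diverge).
* **Perimeter** uses Moore-neighbour boundary tracing with the
  Vossepoel-Smeulders chain-code weights (0.980/1.406 per axial/diagonal
  step, -0.091 per corner), accurate to ~1% on digital disks, so disk
  circularity lands in [0.95, 1].
* **Texture** (GLCM) features quantize each nucleus min-max to 64 gray
  levels and average 1-px offsets at 0/45/90/135 degrees, making them
  comparable across staining depth and robust (< 5%) to 90-degree
  rotations. Flat nuclei take their degenerate values (contrast 0, energy
  1, correlation defined as 0).
* **LDA** is the closed-form two-class discriminant on standardized
  features with the pooled covariance shrunk toward its diagonal
  (automatic intensity p/(p + n_train) plus a 1e-8 ridge). Balancing
  downsamples the majority class (seeded) before a stratified 75/25
  split. The normalized score is min-max over **all** scored nuclei
  (train + test combined) — the contract fixes min 0 / max 1 per scored
  set. Classification threshold is 0 on the centred LDA1 axis.
* **Density clustering** follows the HDBSCAN pipeline: k-NN core
  distances (k = `min_cluster_size`), mutual-reachability MST,
  single-linkage hierarchy, condensed tree, excess-of-mass selection. The
  implementation was validated against the reference library (adjusted
  Rand index 1.0 on blob fixtures). We default `allow_single_cluster =
  TRUE` — unlike the reference library — because a field of view holding
  one homogeneous implant region should be reported as one cluster, not
  as all-noise; with well-separated groups the two behaviours coincide.
* **Statistics.** `compare_groups()` delegates to `wilcox.test`,
  `t.test(paired = TRUE)`, `aov`/`TukeyHSD`; a paired t on identical
  groups (zero variance of differences) is reported as statistic 0,
  p = 1 by convention. No multiple-testing correction is applied across
  channels or genes (per-comparison reporting, stated explicitly).
* **qPCR.** Amplification efficiency is fixed at 2 (classic 2^-ddCt); no
  efficiency calibration is attempted.

# Design decisions where the field leaves room

* The four-group feature catalog is a fixed, testable stand-in for larger
  published chromatin-feature repositories; it is not claimed equivalent
  to any external catalog. One consequence, verified empirically: when two
  populations differ only in `texture_contrast`, the single best separator
  is the per-nucleus intensity SD (texture amplitude *is* intensity
  spread), with GLCM correlation/homogeneity immediately behind — texture
  features dominate all morphology/boundary features but do not always
  hold rank 1.
* The angular statistic for clusters uses the nuclear long-axis (mask
  second-moment) orientation; sections do not define any other per-nucleus
  axis.
* ROI "normalized intensity" is implemented as division by the
  reference-condition mean per channel (background-subtracted), making the
  reference mean fold change identically 1.
* Cluster statistics are computed per condition image, not pooled across
  images.
* Score normalization is global over the scored set rather than
  per-image; per-image normalization would make scores incomparable
  between conditions imaged separately.

# Runtime scaling in the test-suite

The acceptance tests scale Monte-Carlo sizes to keep the default suite
around two minutes: the LDA chance-level control uses 150 nuclei/class
over 25 seeds (the bound [0.45, 0.55] applies to the mean over seeds,
whose standard error at this scale is ~0.012), and the effect-size
monotonicity check uses 10 seeds at each of three effect levels with 100
nuclei/class. Uniformity checks on smoothed orientation fields subsample
pixels on a stride-8 grid so that the chi-square test sees effectively
independent draws (the tensor window correlates neighbouring pixels).

# Known limitations

* Touching nuclei merge; counts in dense implant cores are conservative.
* 2-D only: distances and orientations are in the section plane.
* The LDA accuracy on real tissue reported in the literature (~63-67%)
  depends on unreleased images and is *not* a target of the test suite;
  synthetic accuracies are controlled by the generator's effect sizes.
* The TIFF codec is a deliberate minimal baseline (uncompressed,
  little-endian, grayscale, 8/16-bit unsigned or 32-bit float); it is not
  a general TIFF reader.
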