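# tissuemorph

Quantitative image analysis for implanted-cell experiments in tissue
sections. The package targets the question "do implanted cells of state A
behave differently from state B inside this tissue?" — for example aged
dermal fibroblasts versus mechanically partially-reprogrammed (PR)
fibroblasts implanted into a reconstructed skin model — and answers it
with five imaging readouts plus the accompanying statistics:

* **Nuclear segmentation** from the nuclear-stain (Hoechst) channel by
  combined local + global Otsu thresholding with size/intensity artifact
  filtering.
* **Chromatin morphometrics**: a 24-feature catalog in four groups —
  nuclear morphology (area, perimeter, aspect ratio, eccentricity,
  solidity, extent, equivalent diameter), boundary (circularity, radial
  CV, concave segments), global intensity profile (mean, SD, skewness,
  kurtosis, entropy, p10/p90 ratio, high-intensity fraction) and chromatin
  texture (GLCM contrast/correlation/homogeneity/energy/entropy at 64 gray
  levels averaged over 4 offsets, chromatin-focus count and area
  fraction).
* **Cell-state scoring**: two-class LDA on standardized features
  (diagonal-shrinkage pooled covariance, balanced classes, stratified
  75/25 split); the LDA1 projection min-max normalized to [0, 1] is the
  per-nucleus state score.
* **Spatial statistics**: internuclear pairwise-distance (IPD) matrices
  `IPD_ij = sqrt((x_i - x_j)^2 + (y_i - y_j)^2)` in um, their dispersion
  (sample SD over unique pairs) as a spreading metric, and epsilon-free
  hierarchical density-based clustering (HDBSCAN-style, implemented in the
  package) of nuclei by position + score, with per-cluster mean score and
  mean pairwise axial angular difference.
* **ECM fiber alignment**: per-pixel structure tensor (Gaussian-derivative
  gradients, Gaussian window of scale `sigma`), fiber orientation
  `theta = phi_gradient + 90` wrapped to (-90, 90], coherency
  `(l_max - l_min)/(l_max + l_min)`, HSB orientation maps (hue = angle,
  saturation = coherency, brightness = image), and axial circular
  histogram width `(90/pi) * sqrt(-2 log Rbar)` capped at the 40.51-degree
  uniform limit.
* **Quantification**: ROI intensity fold changes against a reference
  condition, 2^-ddCt relative expression, and Mann-Whitney / Tukey HSD /
  paired t / ANOVA wrappers with the figure star convention.

A synthetic tissue generator (two nucleus populations with controllable
morphology/texture contrast, Gaussian spatial dispersion, oriented fiber
textures) provides ground truth for every stage, so the whole pipeline is
testable without external imaging data.

## Worked example

```r
library(tissuemorph)

old <- population_params(mean_area = 55, texture_contrast = 0.25)
pr  <- population_params(mean_area = 65, texture_contrast = 0.45)
scene_old <- generate_nuclei_scene(old, old, n_per_pop = 40, dispersion = 40,
                                   image_size = 640, pixel_size = 0.5, seed = 1)
scene_pr  <- generate_nuclei_scene(pr, pr, n_per_pop = 40, dispersion = 60,
                                   image_size = 640, pixel_size = 0.5, seed = 2)

seg_old <- segment_nuclei(scene_old$image, 0.5)
seg_pr  <- segment_nuclei(scene_pr$image, 0.5)
ft <- rbind(as.data.frame(compute_features(scene_old$image, seg_old, condition = "old")),
            as.data.frame(compute_features(scene_pr$image, seg_pr, condition = "PR")))
attr(ft, "groups") <- feature_catalog()
class(ft) <- c("feature_table", "data.frame")

ss <- train_score_lda(ft, seed = 1)
print(ss)
#> <score_set> 160 nuclei (old vs PR), test accuracy 1.000, shrinkage 0.167, seed 1
rank_feature_groups(ss, 3)
#>       feature     group coefficient
#> 1      int_sd intensity    2.110857
#> 2    int_mean intensity    2.047687
#> 3 circularity  boundary   -1.593230

ipd_dispersion(compute_ipd_matrix(seg_old))  # 49.1 um
ipd_dispersion(compute_ipd_matrix(seg_pr))   # 61.4 um

f  <- compute_orientation_field(generate_fiber_field(30, 10, 512, seed = 3)$image,
                                sigma = 2, pixel_size = 0.5)
oh <- orientation_histogram(f)
sprintf("fiber mean %.1f deg, width %.1f deg", oh$mean, oh$width)
#> "fiber mean 30.4 deg, width 5.0 deg"
```

Reading the numbers: the two synthetic populations were built 10 um^2 and
0.2 texture-contrast apart, so the classifier separates them perfectly on
held-out nuclei, with intensity-profile features carrying the largest
standardized coefficients. The PR scene was generated with 1.5x the
spatial dispersion of the old scene and its measured IPD dispersion is
correspondingly larger (61.4 vs 49.1 um). The fiber field was generated
with axial mean 30 degrees and concentration 10 (axial SD ~5.7 degrees);
the recovered histogram mean and width match.

End-to-end runs with a serialized config, per-stage CSV/TIFF/PNG outputs
and a summary JSON:

```r
cfg <- default_config(out_dir = "out")
run_rejuvenation_analysis(cfg)  # segment -> features -> LDA -> IPD -> clusters
run_wound_analysis(cfg)         # orientation field -> histogram/width -> HSB
```

There is also a CLI (`inst/cli/tissuemorph`) with subcommands
`simulate nuclei|fibers|points`, `segment`, `features`, `score-states`,
`ipd`, `clusters`, `fibers`, `quantify`, `run-rejuvenation`, `run-wound`,
`init`; `--seed` is mandatory for `simulate`.

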