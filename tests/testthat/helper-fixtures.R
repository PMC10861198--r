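# Shared fixtures, all generated in code.

# Sinusoidal grating with stripes along `angle_deg` (axial, CCW from +x,
# y up), period in pixels.
make_grating <- function(sz, angle_deg, period = 8) {
  a <- angle_deg * pi / 180
  row <- matrix(seq_len(sz), sz, sz)
  col <- t(row)
  x <- col
  y <- sz - row + 1
  sin(2 * pi * (-sin(a) * x + cos(a) * y) / period)
}

# Bright disk on a zero background.
make_disk_image <- function(sz = 64, r = 10, value = 1000,
                            centre = c(sz / 2, sz / 2)) {
  row <- matrix(seq_len(sz), sz, sz)
  col <- t(row)
  ifelse((row - centre[1])^2 + (col - centre[2])^2 <= r^2, value, 0)
}

# Feature table from a synthetic scene using its ground-truth labels
# (segmentation-free), with the population tag as condition.
gt_feature_table <- function(scene) {
  ft <- compute_features(scene$image,
                         list(labels = scene$labels,
                              pixel_size = scene$pixel_size))
  ft$condition <- scene$truth$pop[match(ft$id, scene$truth$id)]
  ft
}

# Default-ish populations kept small enough for fast rendering.
fast_pop <- function(...) {
  do.call(population_params,
          utils::modifyList(list(mean_area = 50), list(...)))
}

# Chi-square uniformity p-value for axial angles from a smoothed field:
# pixels are subsampled on a stride-8 grid so the values entering the test
# are effectively decorrelated (the tensor window correlates neighbours).
uniformity_p <- function(theta_matrix, stride = 8L, n_bins = 16L) {
  sub <- theta_matrix[seq(stride %/% 2, nrow(theta_matrix), stride),
                      seq(stride %/% 2, ncol(theta_matrix), stride)]
  counts <- tabulate(cut(as.vector(sub),
                         seq(-90, 90, length.out = n_bins + 1),
                         labels = FALSE), nbins = n_bins)
  suppressWarnings(stats::chisq.test(counts)$p.value)
}

fast_scene <- function(seed, n_per_pop = 50, pa = fast_pop(), pb = pa,
                       dispersion = 80, image_size = 640) {
  generate_nuclei_scene(pa, pb, n_per_pop = n_per_pop,
                        dispersion = dispersion, image_size = image_size,
                        pixel_size = 0.5, seed = seed)
}
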