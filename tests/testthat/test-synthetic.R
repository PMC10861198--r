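test_that("point patterns are deterministic and scale with dispersion", {
  p1 <- generate_point_pattern(100, 15, seed = 4)
  p2 <- generate_point_pattern(100, 15, seed = 4)
  expect_identical(p1, p2)
  # dispersion zero: all points coincide
  p0 <- generate_point_pattern(10, 0, seed = 1)
  expect_true(all(p0$x_um == 0 & p0$y_um == 0))
  # two points: exactly one distinct off-diagonal IPD value
  m2 <- compute_ipd_matrix(generate_point_pattern(2, 12, seed = 9))
  expect_length(unique(m2[upper.tri(m2)]), 1L)
  # doubling dispersion doubles distances exactly under the same seed
  a <- generate_point_pattern(50, 10, seed = 3)
  b <- generate_point_pattern(50, 20, seed = 3)
  expect_equal(as.vector(dist(b[, c("x_um", "y_um")])),
               2 * as.vector(dist(a[, c("x_um", "y_um")])))
})

test_that("mean IPD of scaled normals doubles with dispersion (Monte-Carlo)", {
  ratios <- vapply(1:50, function(s) {
    m1 <- compute_ipd_matrix(generate_point_pattern(200, 10, seed = s))
    m2 <- compute_ipd_matrix(generate_point_pattern(200, 20, seed = s))
    mean(m2[upper.tri(m2)]) / mean(m1[upper.tri(m1)])
  }, 0)
  expect_equal(mean(ratios), 2, tolerance = 0.05)
})

test_that("fiber fields are deterministic with controllable concentration", {
  f1 <- generate_fiber_field(20, 5, 128, seed = 11)
  f2 <- generate_fiber_field(20, 5, 128, seed = 11)
  expect_identical(f1$image, f2$image)
  # degenerate limit: high concentration pins segment angles to the mean
  fh <- generate_fiber_field(10, 100, 64, seed = 1, n_segments = 5000)
  expect_gte(mean(axial_diff(fh$angles, 10) <= 2), 0.99)
  # concentration 0: uniform segment angles (chi-square over 16 bins)
  fu <- generate_fiber_field(0, 0, 64, seed = 2, n_segments = 5000)
  counts <- tabulate(cut(fu$angles, seq(-90, 90, length.out = 17),
                         labels = FALSE), nbins = 16)
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)
  # axial mean recovered within 1 degree at concentration >= 5
  f5 <- generate_fiber_field(-40, 5, 64, seed = 3, n_segments = 5000)
  expect_lt(axial_diff(axial_mean(f5$angles)$mean, -40), 1)
})

test_that("nuclei scenes are deterministic and carry valid ground truth", {
  s1 <- fast_scene(seed = 7, n_per_pop = 30)
  s2 <- fast_scene(seed = 7, n_per_pop = 30)
  expect_identical(s1$image, s2$image)
  expect_identical(s1$truth, s2$truth)
  expect_equal(nrow(s1$truth), 60)
  expect_setequal(unique(as.vector(s1$labels)), c(0L, s1$truth$id))
  # every nucleus fully inside the image: no labels on the border
  expect_true(all(s1$labels[c(1, nrow(s1$labels)), ] == 0L))
  expect_true(all(s1$labels[, c(1, ncol(s1$labels))] == 0L))
})

test_that("scene dispersion rescales ground-truth pairwise distances", {
  # a sparse scene in a large image, so neither bounds nor overlap reject
  # any placement candidate at either dispersion and the same candidates
  # are accepted in both scenes
  pp <- fast_pop(mean_area = 30)
  sa <- fast_scene(seed = 5, n_per_pop = 4, pa = pp, dispersion = 30,
                   image_size = 1024)
  sb <- fast_scene(seed = 5, n_per_pop = 4, pa = pp, dispersion = 60,
                   image_size = 1024)
  da <- dist(sa$truth[, c("x_um", "y_um")])
  db <- dist(sb$truth[, c("x_um", "y_um")])
  expect_equal(as.vector(db), 2 * as.vector(da), tolerance = 1e-12)
})

test_that("identical populations make tags independent of features", {
  # distributional identity: two-sample test on ground-truth areas pooled
  # over seeds should behave like a null
  pvals <- vapply(1:20, function(s) {
    sc <- fast_scene(seed = 100 + s, n_per_pop = 25, image_size = 512)
    a <- sc$truth$area_um2[sc$truth$pop == "A"]
    b <- sc$truth$area_um2[sc$truth$pop == "B"]
    suppressWarnings(wilcox.test(a, b)$p.value)
  }, 0)
  expect_gt(min(pvals), 0.01 / 20) # no seed wildly significant
  expect_gt(mean(pvals > 0.05), 0.7)
})

test_that("rendered moments match requested population parameters", {
  # n = 500 nuclei accumulated over seeds; 5% tolerance on area and AR
  truth <- do.call(rbind, lapply(1:5, function(s)
    fast_scene(seed = 200 + s, n_per_pop = 50, image_size = 640)$truth))
  expect_equal(mean(truth$area_um2), 50, tolerance = 0.05)
  expect_equal(mean(truth$aspect_ratio), 1.5, tolerance = 0.05)
})

test_that("overcrowded scenes fail with an explicit error", {
  expect_error(
    generate_nuclei_scene(fast_pop(), fast_pop(), n_per_pop = 200,
                          dispersion = 5, image_size = 128,
                          pixel_size = 0.5, seed = 1),
    "scene too crowded")
})

test_that("population parameters are validated", {
  expect_error(population_params(mean_area = -1), "mean_area")
  expect_error(population_params(texture_contrast = 1.5), "texture_contrast")
  expect_error(generate_fiber_field(120, 1, 64, seed = 1), "mean_angle")
})
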