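test_that("analytic shapes produce the expected feature values", {
  img <- make_disk_image(sz = 64, r = 10, value = 1000)
  seg <- segment_nuclei(img, pixel_size = 0.5)
  ft <- compute_features(img, seg)
  expect_equal(nrow(ft), 1L)
  expect_lt(ft$eccentricity, 0.05)
  expect_gte(ft$circularity, 0.95)
  expect_lte(ft$circularity, 1)
  expect_equal(ft$int_sd, 0)
  expect_equal(ft$glcm_contrast, 0)
  expect_equal(ft$glcm_energy, 1)
  expect_equal(ft$int_entropy, 0)
  # axis-aligned 2:1 ellipse
  row <- matrix(1:64, 64, 64); col <- t(row)
  ell <- ifelse(((col - 32) / 20)^2 + ((row - 32) / 10)^2 <= 1, 500, 0)
  ft2 <- compute_features(ell, segment_nuclei(ell, 1, max_area = 4000))
  expect_equal(ft2$aspect_ratio, 2, tolerance = 0.05)
})

test_that("feature catalog covers the four groups consistently", {
  groups <- feature_catalog()
  expect_setequal(unique(groups),
                  c("morphology", "boundary", "intensity", "texture"))
  expect_false(anyDuplicated(names(groups)) > 0)
  sc <- fast_scene(seed = 51, n_per_pop = 10, image_size = 448,
                   dispersion = 40)
  ft <- gt_feature_table(sc)
  expect_s3_class(ft, "feature_table")
  expect_true(all(names(groups) %in% names(ft)))
  expect_identical(feature_groups(ft), groups)
  # no missing values for non-degenerate nuclei
  expect_false(anyNA(ft[!ft$degenerate, names(groups)]))
})

test_that("morphology is intensity-invariant; area/diameter consistent", {
  sc <- fast_scene(seed = 61, n_per_pop = 10, image_size = 448,
                   dispersion = 40)
  seg <- list(labels = sc$labels, pixel_size = sc$pixel_size)
  ft1 <- compute_features(sc$image, seg)
  ft2 <- compute_features(sc$image * 3.7, seg)
  morph <- names(feature_catalog())[feature_catalog() %in%
                                      c("morphology", "boundary")]
  expect_equal(ft1[, morph], ft2[, morph], tolerance = 1e-12)
  expect_equal(ft1$equiv_diameter, 2 * sqrt(ft1$area / pi))
})

test_that("co-occurrence features are robust to 90-degree rotation", {
  sc <- fast_scene(seed = 71, n_per_pop = 6, image_size = 384,
                   dispersion = 30)
  seg <- list(labels = sc$labels, pixel_size = sc$pixel_size)
  ft <- compute_features(sc$image, seg)
  # rotate image and labels by 90 degrees
  rot <- function(m) t(m[nrow(m):1, , drop = FALSE])
  seg_r <- list(labels = rot(sc$labels), pixel_size = sc$pixel_size)
  ft_r <- compute_features(rot(sc$image), seg_r)
  for (f in c("glcm_contrast", "glcm_correlation", "glcm_homogeneity",
              "glcm_energy", "glcm_entropy")) {
    rel <- abs(ft[[f]] - ft_r[[f]]) /
      pmax(abs(ft[[f]]), .Machine$double.eps)
    expect_lt(max(rel), 0.05)
  }
})

test_that("texture-dominated population differences rank as expected", {
  # Populations differing only in texture_contrast (0.1 vs 0.6). Texture
  # amplitude feeds both the texture group and the per-nucleus intensity
  # spread, so the assertion is: texture features dominate every
  # morphology/boundary feature and reach the top-3 effect sizes.
  pa <- fast_pop(texture_contrast = 0.1)
  pb <- fast_pop(texture_contrast = 0.6)
  df <- do.call(rbind, lapply(1:2, function(s)
    as.data.frame(gt_feature_table(
      fast_scene(seed = 300 + s, n_per_pop = 100, pa = pa, pb = pb,
                 dispersion = 90, image_size = 768)))))
  groups <- feature_catalog()
  smd <- vapply(names(groups), function(f) {
    a <- df[[f]][df$condition == "A"]
    b <- df[[f]][df$condition == "B"]
    sp <- sqrt((var(a) + var(b)) / 2)
    if (sp == 0) 0 else abs(mean(a) - mean(b)) / sp
  }, 0)
  ranked <- groups[names(sort(smd, decreasing = TRUE))]
  expect_true("texture" %in% ranked[1:3])
  expect_gt(min(smd[c("glcm_correlation", "glcm_homogeneity")]),
            max(smd[groups %in% c("morphology", "boundary")]))
})

test_that("tiny nuclei are flagged degenerate", {
  img <- matrix(0, 48, 48)
  img[10:12, 10:12] <- 800          # 9 px: degenerate
  img[25:40, 25:40] <- 800          # large: fine
  seg <- segment_nuclei(img, 0.5, min_area = 0.5, max_area = 400)
  ft <- compute_features(img, seg)
  expect_equal(sum(ft$degenerate), 1L)
  expect_equal(ft$degenerate, ft$n_px < 16)
})
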