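test_that("constant images give zero energy and coherency", {
  f <- compute_orientation_field(matrix(7, 32, 32), sigma = 2,
                                 pixel_size = 1)
  expect_true(all(f$energy == 0))
  expect_true(all(f$coherency == 0))
})

test_that("gratings are recovered within 0.5 degree with high coherency", {
  interior <- 20:108
  for (ang in c(-60, -30, 0, 30, 60)) {
    f <- compute_orientation_field(make_grating(128, ang), sigma = 4,
                                   pixel_size = 1)
    th <- f$theta[interior, interior]
    expect_lt(median(axial_diff(th, ang)), 0.5)
    expect_gte(median(f$coherency[interior, interior]), 0.95)
  }
})

test_that("white noise is incoherent with uniform angles", {
  set.seed(37)
  cohs <- pvals <- numeric(10)
  for (s in 1:10) {
    f <- compute_orientation_field(matrix(rnorm(96^2), 96, 96),
                                   sigma = 2, pixel_size = 1)
    cohs[s] <- mean(f$coherency)
    pvals[s] <- uniformity_p(f$theta)
  }
  expect_lt(max(cohs), 0.3)
  expect_gt(median(pvals), 0.01)
})

test_that("coherency is bounded in [0, 1] on fuzzed inputs", {
  set.seed(41)
  for (i in 1:5) {
    img <- matrix(runif(48^2)^sample(1:3, 1) * 10^sample(-2:3, 1), 48, 48)
    f <- compute_orientation_field(img, sigma = runif(1, 0.5, 4),
                                   pixel_size = 1)
    expect_true(all(f$coherency >= 0 & f$coherency <= 1))
    expect_true(all(f$energy >= 0))
    expect_true(all(f$theta > -90 & f$theta <= 90))
  }
})

test_that("rotating the image by 90 degrees rotates recovered angles", {
  img <- generate_fiber_field(25, 8, 128, seed = 43)$image
  f1 <- compute_orientation_field(img, sigma = 2, pixel_size = 1)
  rot <- t(img[nrow(img):1, ]) # 90-degree rotation
  f2 <- compute_orientation_field(rot, sigma = 2, pixel_size = 1)
  w <- f1$coherency * f1$energy
  m1 <- axial_mean(as.vector(f1$theta), as.vector(w))$mean
  w2 <- f2$coherency * f2$energy
  m2 <- axial_mean(as.vector(f2$theta), as.vector(w2))$mean
  expect_lt(axial_diff(m2, m1 + 90), 1)
})

test_that("orientation histograms summarize alignment correctly", {
  f <- compute_orientation_field(make_grating(128, 30), sigma = 4,
                                 pixel_size = 1)
  oh <- orientation_histogram(f)
  expect_lte(oh$width, 2)
  expect_lt(axial_diff(oh$mean, 30), 1)
  # reference angle re-expresses the mean
  oh2 <- orientation_histogram(f, reference_angle = 30)
  expect_lt(abs(oh2$mean), 1)
  expect_equal(sum(oh$weight), sum(oh2$weight))
  # uniform axial angles: width at the uniform limit
  set.seed(47)
  ohu <- orientation_histogram(runif(1e5, -90, 90), n_bins = 18)
  expect_equal(ohu$width, 40.51, tolerance = 0.025)
  # concentration ordering from the generator
  wd <- vapply(c(20, 0), function(k) {
    img <- generate_fiber_field(10, k, 192, seed = 53)$image
    orientation_histogram(compute_orientation_field(img, 2, 1))$width
  }, 0)
  expect_lt(wd[1], wd[2])
  expect_error(orientation_histogram(f, mask = matrix(FALSE, 128, 128)),
               "empty mask")
})

test_that("HSB maps encode orientation in hue and desaturate flatness", {
  fconst <- compute_orientation_field(matrix(3, 32, 32), sigma = 2,
                                      pixel_size = 1)
  rgb <- render_hsb_map(fconst, matrix(3, 32, 32), legend = FALSE)
  expect_equal(rgb[, , 1], rgb[, , 2]) # grayscale: R = G = B
  expect_equal(rgb[, , 2], rgb[, , 3])
  g <- make_grating(64, 30)
  fg <- compute_orientation_field(g, sigma = 4, pixel_size = 1)
  rgbg <- render_hsb_map(fg, g, legend = FALSE)
  # decode hue back to an angle at a high-coherency interior pixel
  px <- rgbg[32, 32, ]
  mx <- max(px); mn <- min(px)
  h6 <- if (mx == px[1]) ((px[2] - px[3]) / (mx - mn)) %% 6
    else if (mx == px[2]) (px[3] - px[1]) / (mx - mn) + 2
    else (px[1] - px[2]) / (mx - mn) + 4
  ang <- (h6 / 6) * 180 - 90
  expect_lt(axial_diff(ang, 30), 2)
  # two half-images with orthogonal gratings: the two dominant modes sit
  # at 0 and 90 degrees (the seam contributes a little weight elsewhere)
  img2 <- cbind(make_grating(64, 0)[, 1:32], make_grating(64, 90)[, 1:32])
  f2 <- compute_orientation_field(img2, sigma = 3, pixel_size = 1)
  oh <- orientation_histogram(f2, n_bins = 12)
  centres <- (oh$bin_left + oh$bin_right) / 2
  top2 <- centres[order(oh$weight, decreasing = TRUE)[1:2]]
  expect_true(any(axial_diff(top2, 0) < 15))
  expect_true(any(axial_diff(top2, 90) < 15))
})
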