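test_that("IPD matrix matches hand values and a brute-force oracle", {
  rec <- data.frame(id = 1:2, x_um = c(0, 3), y_um = c(0, 4))
  m <- compute_ipd_matrix(rec)
  expect_equal(unname(m[1, 2]), 5)
  expect_equal(unname(diag(m)), c(0, 0))
  # brute-force all-pairs oracle on 100 random points, exact
  set.seed(13)
  pts <- data.frame(id = 1:100, x_um = runif(100, 0, 500),
                    y_um = runif(100, 0, 500))
  m2 <- compute_ipd_matrix(pts)
  oracle <- matrix(0, 100, 100)
  for (i in 1:100) for (j in 1:100)
    oracle[i, j] <- sqrt((pts$x_um[i] - pts$x_um[j])^2 +
                           (pts$y_um[i] - pts$y_um[j])^2)
  expect_equal(unname(unclass(m2)), oracle)
  expect_identical(unclass(m2), t(unclass(m2)))
  # homogeneity: scaling coordinates scales every entry
  pts2 <- transform(pts, x_um = 2 * x_um, y_um = 2 * y_um)
  expect_equal(unclass(compute_ipd_matrix(pts2)), 2 * unclass(m2))
  expect_error(compute_ipd_matrix(data.frame(id = c(1, 1),
                                             x_um = 1:2, y_um = 1:2)),
               "duplicate")
})

test_that("ipd_dispersion matches hand computation and invariances", {
  col <- data.frame(id = 1:3, x_um = c(0, 1, 2), y_um = 0)
  expect_equal(ipd_dispersion(compute_ipd_matrix(col)), sd(c(1, 1, 2)))
  expect_equal(round(ipd_dispersion(compute_ipd_matrix(col)), 4), 0.5774)
  # coincident points
  same <- data.frame(id = 1:4, x_um = 1, y_um = 2)
  expect_equal(ipd_dispersion(compute_ipd_matrix(same)), 0)
  # n = 2: single pair, reported as 0 with a note
  expect_message(
    d2 <- ipd_dispersion(compute_ipd_matrix(
      data.frame(id = 1:2, x_um = c(0, 9), y_um = 0))), "one nucleus pair")
  expect_equal(d2, 0)
  # translation/rotation invariance, linear scaling
  set.seed(17)
  pts <- data.frame(id = 1:60, x_um = rnorm(60, 0, 30),
                    y_um = rnorm(60, 0, 30))
  d0 <- ipd_dispersion(compute_ipd_matrix(pts))
  th <- 0.7
  rot <- transform(pts,
                   x_um = cos(th) * x_um - sin(th) * y_um + 100,
                   y_um = sin(th) * x_um + cos(th) * y_um - 50)
  expect_equal(ipd_dispersion(compute_ipd_matrix(rot)), d0,
               tolerance = 1e-12)
  scl <- transform(pts, x_um = 3 * x_um, y_um = 3 * y_um)
  expect_equal(ipd_dispersion(compute_ipd_matrix(scl)), 3 * d0)
})

test_that("generator dispersion doubles the IPD dispersion (Monte-Carlo)", {
  ratios <- vapply(1:50, function(s) {
    d1 <- ipd_dispersion(compute_ipd_matrix(
      generate_point_pattern(200, 10, seed = 1000 + s)))
    d2 <- ipd_dispersion(compute_ipd_matrix(
      generate_point_pattern(200, 20, seed = 1000 + s)))
    d2 / d1
  }, 0)
  expect_equal(mean(ratios), 2, tolerance = 0.05)
})

test_that("planted blobs are recovered with their scores and sizes", {
  set.seed(23)
  n <- 80
  rec <- data.frame(
    id = seq_len(2 * n),
    x_um = c(rnorm(n, 0, 20), rnorm(n, 500, 20)),
    y_um = rnorm(2 * n, 0, 20),
    score = c(rnorm(n, 0.2, 0.02), rnorm(n, 0.8, 0.02)))
  ca <- cluster_nuclei(rec, min_cluster_size = 5)
  expect_equal(nrow(ca$clusters), 2L)
  expect_equal(sort(ca$clusters$mean_score), c(0.2, 0.8), tolerance = 0.25)
  expect_true(all(abs(sort(ca$clusters$mean_score) - c(0.2, 0.8)) < 0.05))
  expect_true(all(ca$clusters$n >= 5))
  # planted-label agreement >= 0.9 (fraction correctly co-assigned)
  planted <- rep(1:2, each = n)
  tab <- table(ca$labels[ca$labels > 0], planted[ca$labels > 0])
  expect_gte(sum(apply(tab, 1, max)) / (2 * n), 0.9)
})

test_that("single blob clusters together; tiny n is all noise", {
  set.seed(29)
  rec <- data.frame(id = 1:100, x_um = rnorm(100, 0, 15),
                    y_um = rnorm(100, 0, 15), score = runif(100, 0.4, 0.6))
  ca <- cluster_nuclei(rec, min_cluster_size = 5)
  expect_equal(nrow(ca$clusters), 1L)
  expect_gte(max(ca$clusters$n), 90)
  expect_message(ca2 <- cluster_nuclei(rec, min_cluster_size = 200),
                 "noise")
  expect_true(all(ca2$labels == -1L))
  expect_equal(nrow(ca2$clusters), 0L)
})

test_that("cluster angular differences wrap axially", {
  rec <- data.frame(id = 1:12,
                    x_um = rep(c(0, 500), each = 6) + runif(12, 0, 10),
                    y_um = runif(12, 0, 10),
                    score = rep(c(0.2, 0.8), each = 6),
                    orientation_deg = c(rep(40, 6),
                                        rep(c(10, 170), 3)))
  ca <- cluster_nuclei(rec, min_cluster_size = 3)
  ca <- cluster_angular_difference(ca, rec)
  expect_equal(nrow(ca$clusters), 2L)
  v <- sort(ca$clusters$mean_angular_diff_deg)
  expect_equal(v[1], 0)
  # 6 nuclei alternating 10/170: mean pairwise axial difference
  expect_equal(v[2], mean_pairwise_axial_diff(rep(c(10, 170), 3)))
  expect_true(all(v >= 0 & v <= 90))
})
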