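test_that("intensity fold changes follow the reference-mean convention", {
  m <- data.frame(channel = "col1",
                  condition = c("old", "old", "PR", "PR"),
                  mean_intensity = c(100, 120, 330, 330))
  fc <- intensity_fold_change(m, "old")
  s <- attr(fc, "summary")
  expect_equal(s$mean_fold_change[s$condition == "PR"], 3)
  expect_equal(s$mean_fold_change[s$condition == "old"], 1)
  # identical treated values -> fold 1; doubling -> fold 2
  m2 <- data.frame(channel = "eln", condition = rep(c("old", "PR"), 3),
                   mean_intensity = rep(c(40, 40), 3))
  s2 <- attr(intensity_fold_change(m2, "old"), "summary")
  expect_equal(s2$mean_fold_change, c(1, 1))
  m2$mean_intensity[m2$condition == "PR"] <- 80
  s3 <- attr(intensity_fold_change(m2, "old"), "summary")
  expect_equal(s3$mean_fold_change[s3$condition == "PR"], 2)
  # background subtraction and failure mode
  m2$background <- 40
  expect_error(intensity_fold_change(m2, "old"), "reference mean <= 0")
})

test_that("ddct fold changes match the closed form and are Ct-shift safe", {
  r <- data.frame(sample = c("t1", "r1"),
                  condition = c("treated", "reference"),
                  ct_target = c(20, 23), ct_housekeeping = c(18, 18))
  out <- ddct_fold_change(r)
  expect_equal(out$ddct[out$sample == "t1"], -3)
  expect_equal(out$fold_change[out$sample == "t1"], 8)
  expect_equal(out$fold_change[out$sample == "r1"], 1)
  # treated dCt equal to reference mean -> fold 1; ddct = -1 -> fold 2
  r2 <- data.frame(sample = c("t", "r"), condition = c("treated",
                                                       "reference"),
                   ct_target = c(22, 22), ct_housekeeping = c(19, 19))
  expect_equal(ddct_fold_change(r2)$fold_change, c(1, 1))
  r2$ct_target[1] <- 21
  expect_equal(ddct_fold_change(r2)$fold_change[1], 2)
  # adding a constant to every Ct leaves folds unchanged
  r3 <- r
  r3$ct_target <- r3$ct_target + 4.5
  r3$ct_housekeeping <- r3$ct_housekeeping + 4.5
  expect_equal(ddct_fold_change(r3)$fold_change,
               ddct_fold_change(r)$fold_change)
  # missing housekeeping Ct skipped with warning
  r4 <- rbind(r, data.frame(sample = "t2", condition = "treated",
                            ct_target = 21, ct_housekeeping = NA))
  expect_warning(out4 <- ddct_fold_change(r4), "skipped")
  expect_equal(nrow(out4), 2L)
})

test_that("group comparisons expose the expected statistics and stars", {
  # complete separation: first group's U statistic is 0
  mw <- compare_groups(list(a = 1:10, b = 11:20), "mann_whitney")
  expect_equal(mw$statistic, 0)
  expect_equal(mw$stars, "***")
  # identical paired groups: statistic 0, p = 1 by convention
  pt <- compare_groups(list(a = c(1, 2, 3), b = c(1, 2, 3)), "paired_t")
  expect_equal(pt$statistic, 0)
  expect_equal(pt$p_value, 1)
  expect_error(compare_groups(list(a = 1:3, b = 1:4), "paired_t"),
               "equal-length")
  expect_error(compare_groups(list(a = 1:3, b = 1:3, c = 1:3),
                              "mann_whitney"), "exactly 2")
  # tukey returns all pairwise comparisons
  set.seed(5)
  tk <- compare_groups(list(a = rnorm(10), b = rnorm(10) + 5,
                            c = rnorm(10)), "tukey_hsd")
  expect_equal(nrow(tk), 3L)
  av <- compare_groups(list(a = rnorm(10), b = rnorm(10)), "anova")
  expect_true(av$p_value > 0 && av$p_value <= 1)
})

test_that("wrapper p-values match the underlying implementations", {
  set.seed(11)
  a <- rnorm(20); b <- rnorm(20) + 0.5
  expect_equal(compare_groups(list(a = a, b = b), "mann_whitney")$p_value,
               suppressWarnings(wilcox.test(a, b)$p.value),
               tolerance = 1e-6)
  expect_equal(compare_groups(list(a = a, b = b), "paired_t")$p_value,
               t.test(a, b, paired = TRUE)$p.value, tolerance = 1e-6)
})

test_that("small groups are flagged unreliable but still reported", {
  expect_message(res <- compare_groups(list(a = c(1, 2), b = c(5, 6)),
                                       "mann_whitney"), "unreliable")
  expect_false(res$reliable)
  expect_true(is.finite(res$p_value))
})
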