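test_that("angle binning follows the half-open convention and conserves counts", {
  expect_equal(unname(bin_angles(c(0, 15, 29.9))$counts), c(3L, 0L, 0L))
  expect_equal(unname(bin_angles(c(10, 45, 80))$counts), c(1L, 1L, 1L))
  # boundaries: 30 is oblique, 60 and 90 perpendicular
  expect_equal(unname(bin_angles(c(30, 60, 90))$counts), c(0L, 1L, 2L))
  expect_error(bin_angles(c(10, 95)), "position\\(s\\) 2")
  expect_error(bin_angles(c(-0.1)), "\\[0, 90\\]")
  # partition property on random valid angles
  set.seed(4)
  a <- runif(500, 0, 90)
  bp <- bin_angles(a)
  expect_equal(sum(bp$counts), 500L)
  expect_equal(sum(bp$proportions), 1)
})

test_that("radial histogram conserves counts with the last bin closed at 90", {
  empty <- radial_histogram(numeric(0))
  expect_equal(sum(empty$count), 0L)
  expect_equal(nrow(empty), 9L)
  h5 <- radial_histogram(rep(5, 12), bin_width_deg = 10)
  expect_equal(h5$count, c(12L, rep(0L, 8L)))
  expect_equal(sum(radial_histogram(c(0, 90, 89.999, 30))$count), 4L)
  expect_error(radial_histogram(c(10), bin_width_deg = 7), "divide")
  # uniform sample: each 10-degree bin within 3 SE of n/9
  set.seed(11)
  u <- runif(9000, 0, 90)
  h <- radial_histogram(u)
  se <- sqrt(9000 * (1 / 9) * (8 / 9))
  expect_true(all(abs(h$count - 1000) < 3.5 * se))
})

test_that("chi-squared on binned counts matches the hand-computed statistic", {
  res <- chi_squared_bins(c(50, 30, 20), c(20, 30, 50))
  # expected counts (35, 30, 35) per group: X^2 = 4 * 225/35 = 25.714...
  expect_equal(res$statistic, 180 / 7, tolerance = 1e-10)
  expect_equal(res$df, 2)
  expect_equal(res$p_value,
               pchisq(180 / 7, df = 2, lower.tail = FALSE))
  # symmetric in group order
  swapped <- chi_squared_bins(c(20, 30, 50), c(50, 30, 20))
  expect_equal(swapped$statistic, res$statistic)
  # identical groups: statistic 0, p = 1
  same <- chi_squared_bins(c(10, 10, 10), c(10, 10, 10))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  # a bin empty in both groups is dropped with df reduced and a warning
  expect_warning(dropped <- chi_squared_bins(c(40, 0, 20), c(25, 0, 35)),
                 "zero total")
  expect_equal(dropped$df, 1)
  # small expected counts flag a note instead of failing
  low <- chi_squared_bins(c(3, 2, 1), c(1, 2, 3))
  expect_match(low$note, "below 5")
  expect_error(chi_squared_bins(c(0, 0, 0), c(1, 1, 1)), "positive")
})

test_that("two-sample KS distance matches ECDF enumeration", {
  expect_equal(ks_two_sample(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
  expect_equal(ks_two_sample(c(1, 2), c(5, 6, 7))$statistic, 1)
  expect_equal(ks_two_sample(c(10, 20, 30), c(10, 20, 30, 70))$statistic,
               0.25)
  expect_error(ks_two_sample(numeric(0), c(1)), "non-empty")
})

test_that("the genotype-by-bin interaction ANOVA matches stats::aov and handles degeneracy", {
  set.seed(21)
  pa <- proportions_table(rep(c("ctrl", "mut"), c(4, 5)),
                          {
                            m <- matrix(runif(27), 9)
                            m / rowSums(m)
                          })
  res <- proportions_anova(pa)
  long <- data.frame(
    g = factor(rep(pa$genotype, 3)),
    b = factor(rep(c("p", "o", "q"), each = 9)),
    y = c(pa$parallel, pa$oblique, pa$perpendicular))
  tab <- summary(stats::aov(y ~ g * b, data = long))[[1L]]
  rn <- trimws(rownames(tab))
  expect_equal(res$statistic, tab[rn == "g:b", "F value"], tolerance = 1e-10)
  expect_equal(res$p_value, tab[rn == "g:b", "Pr(>F)"], tolerance = 1e-10)

  # identical proportions everywhere: no interaction, p = 1
  flat <- proportions_table(rep(c("a", "b"), each = 3),
                            matrix(rep(c(0.2, 0.3, 0.5), 6), 6,
                                   byrow = TRUE))
  expect_equal(proportions_anova(flat)$p_value, 1)

  # deterministic separation with zero within-group variance: p = 0
  sep <- proportions_table(
    rep(c("a", "b"), each = 5),
    rbind(matrix(rep(c(0.4, 0.2, 0.4), 5), 5, byrow = TRUE),
          matrix(rep(c(0.17, 0.23, 0.60), 5), 5, byrow = TRUE)))
  res_sep <- proportions_anova(sep)
  expect_equal(res_sep$p_value, 0)
  expect_true(is.infinite(res_sep$statistic))

  expect_error(proportions_anova(proportions_table(c("a", "a", "b"),
                                                   diag(3))),
               "fewer than 2")
})

test_that("permutation-calibrated interaction p-values are approximately uniform under the null", {
  mix <- angle_mixture(c(1, 1, 1) / 3, c(15, 45, 75), c(9, 9, 9))
  set.seed(606)
  ps <- replicate(150, {
    pr <- t(sapply(1:10, function(i) {
      bin_angles(epistrat:::.rmixture(30, mix))$proportions
    }))
    pa <- proportions_table(rep(c("a", "b"), each = 5), pr)
    proportions_anova(pa, n_permutations = 79)$p_value
  })
  expect_lt(abs(mean(ps) - 0.5), 0.1)
  expect_lte(mean(ps <= 0.05), 0.12)
  expect_gte(mean(ps <= 0.5), 0.35)
})

test_that("the pooled-variance t-test matches its contracts", {
  same <- compare_group_means(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  # matches stats::t.test with var.equal = TRUE
  a <- c(1.2, 3.1, 2.2, 4.0)
  b <- c(2.5, 3.9, 4.4)
  res <- compare_group_means(a, b)
  ht <- t.test(a, b, var.equal = TRUE)
  expect_equal(res$statistic, unname(ht$statistic))
  expect_equal(res$p_value, ht$p.value)
  # separated constant groups: p -> 0 as jitter vanishes
  ps <- vapply(c(1e-2, 1e-4, 1e-6), function(eps) {
    compare_group_means(c(0, 0, 0, 0) + c(0, eps, 0, -eps),
                        c(1, 1, 1, 1))$p_value
  }, numeric(1L))
  expect_true(all(diff(ps) < 0))
  expect_equal(compare_group_means(c(0, 0, 0), c(1, 1, 1))$p_value, 0)
  expect_equal(compare_group_means(c(1, 1), c(1, 1))$p_value, 1)
})

test_that("chi-squared type-I error is ~5% under a shared mixture and power >80% for the presets", {
  mixes <- default_angle_mixtures()
  null_mix <- mixes[["control@15.5"]]
  set.seed(37)
  rej_null <- mean(replicate(1000, {
    chi_squared_bins(
      bin_angles(epistrat:::.rmixture(100, null_mix))$counts,
      bin_angles(epistrat:::.rmixture(100, null_mix))$counts)$p_value < 0.05
  }))
  expect_gte(rej_null, 0.03)
  expect_lte(rej_null, 0.07)

  rej_alt <- mean(replicate(500, {
    chi_squared_bins(
      bin_angles(epistrat:::.rmixture(100, mixes[["control@16.5"]]))$counts,
      bin_angles(epistrat:::.rmixture(100, mixes[["mutant@16.5"]]))$counts
    )$p_value < 0.05
  }))
  expect_gt(rej_alt, 0.8)
})
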