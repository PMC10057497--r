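test_that("the t field equals the scalar two-sample t at every node", {
  set.seed(41)
  a <- matrix(rnorm(4 * 12), 4, 12)
  b <- matrix(rnorm(5 * 12, mean = 0.4), 5, 12)
  tf <- t_field(a, b)
  expect_equal(tf$df, 7)
  oracle <- vapply(seq_len(12), function(q) {
    unname(stats::t.test(a[, q], b[, q], var.equal = TRUE)$statistic)
  }, numeric(1))
  expect_equal(tf$t, oracle, tolerance = 1e-10)

  expect_equal(t_field(matrix(rnorm(12 * 5), 6), matrix(rnorm(12 * 5), 6))$df, 10)
  expect_equal(t_field(matrix(rnorm(12 * 5), 6), matrix(rnorm(16 * 5), 8))$df, 12)

  same <- rbind(sin(1:20), cos(1:20))
  expect_equal(t_field(same, same)$t, rep(0, 20))

  flat <- rbind(rep(1, 8), rep(1, 8))
  expect_error(t_field(flat, rbind(rep(2, 8), rep(2, 8))), "zero pooled variance")
})

test_that("residual smoothness estimation recovers the smoothing kernel FWHM", {
  r <- smooth_gaussian_curves(50, 200, 20, seed = 7)
  resid <- sweep(r, 2, colMeans(r))
  est <- estimate_fwhm(resid, df = 49)
  expect_lt(abs(est - 20) / 20, 0.15)

  est10 <- estimate_fwhm(smooth_gaussian_curves(50, 200, 10, seed = 8), df = 49)
  est40 <- estimate_fwhm(smooth_gaussian_curves(50, 200, 40, seed = 9), df = 49)
  expect_lt(est10, est40)

  # residuals proportional to a fixed curve: finite positive estimate
  base <- sin(seq(0, 3 * pi, length.out = 50)) + 2
  pm <- rbind(base, -base, base, -base)
  est_pm <- estimate_fwhm(pm, df = 2)
  expect_true(is.finite(est_pm) && est_pm > 0)

  expect_error(estimate_fwhm(matrix(0, 4, 30)), "all-zero")
})

test_that("the RFT threshold sits between uncorrected and Bonferroni and is monotone", {
  df <- 12; Q <- 200; alpha <- 0.05
  for (fwhm in c(5, 15, 60)) {
    u <- rft_threshold(df, fwhm, Q, alpha)
    expect_gt(u, qt(1 - alpha, df))
    expect_lt(u, qt(1 - alpha / Q, df))
  }
  # infinite smoothness: no multiplicity left, uncorrected quantile
  expect_equal(rft_threshold(df, 1e9, Q, alpha), qt(1 - alpha, df),
               tolerance = 1e-4)
  # monotone: stricter alpha and more resels both raise the threshold
  expect_gt(rft_threshold(df, 15, Q, 0.01), rft_threshold(df, 15, Q, 0.05))
  expect_gt(rft_threshold(df, 10, Q, alpha), rft_threshold(df, 20, Q, alpha))
})

test_that("permutation threshold matches exhaustive enumeration on a tiny design", {
  # constant curves per subject: the t field is flat, so max|t| per
  # labelling is the scalar |t| of the subject values
  vals <- c(0, 0.5, 2, 3)
  curves <- matrix(vals, 4, 3)   # 4 subjects x 3 nodes, constant rows
  oracle <- apply(combn(4, 2), 2, function(idx) {
    abs(unname(stats::t.test(vals[idx], vals[-idx], var.equal = TRUE)$statistic))
  })
  expected <- unname(quantile(oracle, 0.75, type = 7))
  got <- permutation_threshold(curves[1:2, ], curves[3:4, ], alpha = 0.25,
                               n_perm = 100)
  expect_equal(got, expected, tolerance = 1e-10)

  # too few distinct labellings for the requested alpha
  expect_error(permutation_threshold(curves[1:2, ], curves[3:4, ],
                                     alpha = 0.05, n_perm = 100),
               "distinct label permutations")
})

test_that("random-subset permutation thresholds are seed-reproducible", {
  a <- smooth_gaussian_curves(8, 60, 10, seed = 1)
  b <- smooth_gaussian_curves(8, 60, 10, seed = 2)
  t1 <- permutation_threshold(a, b, n_perm = 200, seed = 9)
  t2 <- permutation_threshold(a, b, n_perm = 200, seed = 9)
  expect_identical(t1, t2)
})

test_that("SPM respects label-swap antisymmetry and location invariance", {
  a <- smooth_gaussian_curves(6, 120, 12, seed = 3)
  b <- smooth_gaussian_curves(6, 120, 12, seed = 4) + 0.8
  s_ab <- spm_ttest2(a, b)
  s_ba <- spm_ttest2(b, a)
  expect_equal(s_ab$t, -s_ba$t, tolerance = 1e-12)
  expect_equal(s_ab$threshold, s_ba$threshold, tolerance = 1e-12)
  expect_identical(s_ab$clusters, s_ba$clusters)

  s_shift <- spm_ttest2(a + 5.7, b + 5.7)
  expect_equal(s_ab$t, s_shift$t, tolerance = 1e-9)
  expect_equal(s_ab$fwhm, s_shift$fwhm, tolerance = 1e-9)
  expect_identical(s_ab$clusters, s_shift$clusters)

  same <- smooth_gaussian_curves(4, 120, 12, seed = 5)
  expect_equal(nrow(spm_ttest2(same, same + 1e-9 * 0)$clusters), 0)
})

test_that("balanced subsampling is seeded and reduces the larger group", {
  a <- smooth_gaussian_curves(8, 100, 12, seed = 6)
  b <- smooth_gaussian_curves(6, 100, 12, seed = 7)
  s1 <- spm_ttest2(a, b, balance_seed = 5)
  s2 <- spm_ttest2(a, b, balance_seed = 5)
  expect_equal(s1$n1, 6)
  expect_equal(s1$df, 10)
  expect_true(s1$metadata$balanced)
  expect_identical(s1$t, s2$t)
})

test_that("tidy and glance expose the SPM fit in broom shape", {
  a <- smooth_gaussian_curves(6, 80, 10, seed = 8)
  b <- smooth_gaussian_curves(6, 80, 10, seed = 9) + 2
  s <- spm_ttest2(a, b)
  td <- tidy(s)
  expect_equal(nrow(td), 80)
  expect_named(td, c("node", "t", "threshold", "significant"))
  expect_equal(sum(td$significant),
               sum(s$clusters$end - s$clusters$start + 1))
  gl <- glance(s)
  expect_equal(gl$df, 10)
  expect_equal(gl$n_clusters, nrow(s$clusters))
})
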