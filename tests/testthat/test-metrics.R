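test_that("relative difference maps implement the percent definition", {
  ref <- wet_map(matrix(100, 3, 3), spacing = c(1, 1))
  m <- wet_map(matrix(101, 3, 3), spacing = c(1, 1))
  d <- relative_diff_map(m, ref)
  expect_true(all(abs(d$values - 1) < 1e-12))
  d0 <- relative_diff_map(ref, ref)
  expect_true(all(d0$values == 0))
  # the printed WET extremes of the imaged region
  d5 <- relative_diff_map(wet_map(matrix(90, 2, 2), spacing = c(1, 1)),
                          wet_map(matrix(180, 2, 2), spacing = c(1, 1)))
  expect_true(all(d5$values == -50))
  # sub-mm reference pixels are masked out
  refs <- wet_map(matrix(c(0.5, 100, 100, 100), 2, 2), spacing = c(1, 1))
  ms <- wet_map(matrix(100, 2, 2), spacing = c(1, 1))
  expect_false(relative_diff_map(ms, refs)$mask[1, 1])
  expect_error(relative_diff_map(bumpy_map(5, 5), ref), "mismatch")
})

test_that("MAPE and RMSPE match hand-computed values", {
  d <- diff_map(matrix(c(1, -1, 2), 1, 3))
  expect_equal(mape(d), 4 / 3)
  expect_equal(rmspe(d), sqrt(2))
  z <- diff_map(matrix(0, 2, 2))
  expect_equal(mape(z), 0)
  cc <- diff_map(matrix(2.5, 2, 2))
  expect_equal(rmspe(cc), 2.5)
  empty <- diff_map(matrix(1, 2, 2), mask = matrix(FALSE, 2, 2))
  expect_error(mape(empty), "empty")
  expect_error(rmspe(empty), "empty")
})

test_that("MAPE never exceeds RMSPE", {
  for (s in 1:20) {
    v <- with_seed_test(s, matrix(rnorm(300, sd = runif(1, 0.1, 3),
                                        mean = runif(1, -2, 2)), 20, 15))
    d <- diff_map(v)
    expect_lte(mape(d), rmspe(d) + 1e-12)
  }
})

test_that("subregion standard errors behave like standard errors", {
  expect_equal(subregion_uncertainty(diff_map(matrix(1.5, 14, 12)))$mape_se, 0)
  # two regions with MAPEs 1 and 2: SE = sd(c(1,2))/sqrt(2) = 0.5
  v <- cbind(matrix(1, 4, 2), matrix(2, 4, 2))
  se2 <- subregion_uncertainty(diff_map(v), n_regions = 2L)
  expect_equal(se2$mape_se, 0.5)
  # on an i.i.d. Gaussian map the subregion SE estimates the standard error
  # of the whole-image MAPE, independent of the partition: sd(|x|)/sqrt(N)
  big <- with_seed_test(3, diff_map(matrix(rnorm(84 * 84), 84, 84)))
  analytic <- sqrt(1 - 2 / pi) / 84
  expect_equal(subregion_uncertainty(big, 42L)$mape_se, analytic,
               tolerance = 0.25)
  expect_equal(subregion_uncertainty(big, 6L)$mape_se, analytic,
               tolerance = 0.35)
  # empty regions are dropped with a warning
  vv <- matrix(1, 10, 10)
  mm <- matrix(TRUE, 10, 10)
  mm[1:5, ] <- FALSE
  expect_warning(subregion_uncertainty(diff_map(vv, mask = mm), 4L), "empty")
})

test_that("folded-normal closed form agrees with Monte Carlo", {
  # zero-mean special case: E|X| = sigma * sqrt(2/pi)
  fn0 <- folded_normal_stats(0, 2)
  expect_equal(fn0$mape, 2 * sqrt(2 / pi), tolerance = 1e-12)
  expect_equal(fn0$rmspe, 2, tolerance = 1e-12)
  for (p in list(c(0.602, 1.33), c(0.266, 1.16), c(-0.4, 0.8))) {
    mc <- with_seed_test(13, mean(abs(rnorm(1e6, p[1], p[2]))))
    fn <- folded_normal_stats(p[1], p[2])
    expect_equal(fn$mape, mc, tolerance = 0.005)
    expect_equal(fn$rmspe, sqrt(p[1]^2 + p[2]^2), tolerance = 1e-12)
  }
})

test_that("large-sample MAPE of a Gaussian map matches the folded normal", {
  v <- with_seed_test(21, matrix(rnorm(1e6, 0.602, 1.33), 1000, 1000))
  d <- diff_map(v)
  expect_equal(mape(d), folded_normal_stats(0.602, 1.33)$mape,
               tolerance = 0.003)
  expect_equal(rmspe(d), folded_normal_stats(0.602, 1.33)$rmspe,
               tolerance = 0.003)
})

test_that("distribution summaries report std, quartiles and histogram", {
  cst <- distribution_summary(diff_map(matrix(2, 5, 5)))
  expect_equal(cst$std, 0)
  expect_equal(cst$q1, cst$median)
  expect_equal(cst$q3, cst$median)
  pm <- distribution_summary(diff_map(matrix(c(-1, 1), 10, 10)))
  expect_equal(pm$median, 0)
  expect_equal(pm$std, 1, tolerance = 0.02)
  big <- with_seed_test(2, diff_map(matrix(rnorm(1e6), 1000, 1000)))
  s <- distribution_summary(big)
  expect_equal(s$std, 1, tolerance = 0.002)
  expect_equal(sum(s$hist$count), 1e6)
  expect_error(distribution_summary(diff_map(matrix(1, 1, 1))), "at least 2")
})
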