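flat_truth <- function(wet = 135, n1 = 14L, n2 = 9L) {
  wet_map(matrix(wet, n1, n2), spacing = c(1, 1), origin = c(0, 0),
          provenance = "truth")
}

test_that("a 48 x 36 mm region tiles into exactly 12 ROIs of 12 x 12 mm", {
  prior <- wet_map(matrix(135, 50, 25), spacing = c(0.98, 1.5),
                   origin = c(35, 31))
  plan <- plan_energy_painting(prior, c(36, 32, 48, 36), c(12, 12))
  expect_equal(nrow(plan), 12)
  expect_equal(sum(plan$n_px), prod(dim(crop_region(prior, c(36, 32, 48, 36))$values)))
  # a uniform prior inside one window shares a single energy
  expect_equal(length(unique(plan$e0)), 1)
})

test_that("WET intervals outside every calibration window abort planning", {
  prior <- flat_truth(400)
  expect_error(plan_energy_painting(prior, c(0, 0, 12, 9), c(12, 9)),
               "planning error")
  # a single ROI spanning two disjoint windows cannot be painted
  v <- matrix(70, 14, 9); v[8:14, ] <- 210
  wide <- wet_map(v, spacing = c(1, 1), origin = c(0, 0))
  expect_error(plan_energy_painting(wide, c(0, 0, 14, 9), c(14, 9)),
               "planning error")
})

test_that("event simulation is deterministic and has the planned size", {
  truth <- flat_truth()
  curves <- calibration_curves()
  plan <- plan_energy_painting(truth, c(0, 0, 14, 9), c(7, 9), curves)
  ev1 <- simulate_events(truth, plan, curves, n_per_pixel = 3L, seed = 5L)
  ev2 <- simulate_events(truth, plan, curves, n_per_pixel = 3L, seed = 5L)
  expect_identical(ev1, ev2)
  expect_equal(nrow(ev1), 3L * sum(plan$n_px))
  expect_named(ev1, c("entry_x", "entry_y", "exit_x", "exit_y", "de_keV",
                      "e0_MeVu", "roi_id"))
})

test_that("noise-free events over a flat truth carry one dE value", {
  truth <- flat_truth()
  bm <- beam_model()
  curves <- lapply(bm$energies, detector_de_curve, bm = bm, noise_frac = 0)
  plan <- plan_energy_painting(truth, c(2, 2, 10, 6), c(10, 6), curves)
  ev <- simulate_events(truth, plan, curves, n_per_pixel = 5L, seed = 1L,
                        sigma_mcs = 0)
  cu <- wetrad:::roi_curve(curves, plan$e0[1])
  expect_true(all(abs(ev$de_keV - cu$fwd(135)) < 1e-9))
})

test_that("dE straggling matches the 5 percent noise model", {
  truth <- flat_truth()
  curves <- calibration_curves()
  plan <- plan_energy_painting(truth, c(2, 2, 10, 6), c(10, 6), curves)
  ev <- simulate_events(truth, plan, curves, n_per_pixel = 160L, seed = 2L,
                        sigma_mcs = 0)
  expect_gt(nrow(ev), 9000)
  rel <- sd(ev$de_keV) / mean(ev$de_keV)
  expect_equal(rel, 0.05, tolerance = 0.05)
})

test_that("filtering drops out-of-range dE and k-sigma outliers", {
  truth <- flat_truth()
  curves <- calibration_curves()
  plan <- plan_energy_painting(truth, c(2, 2, 10, 6), c(10, 6), curves)
  ev <- simulate_events(truth, plan, curves, n_per_pixel = 10L, seed = 3L,
                        sigma_mcs = 0)
  # tight in-range distribution: nothing dropped by the range rule
  f <- filter_events(ev, curves)
  expect_equal(attr(f, "dropped_range"), 0L)
  # a single zero-dE outlier among in-window events is removed
  bad <- ev[1, ]
  bad$de_keV <- 0
  f2 <- filter_events(rbind(ev, bad), curves)
  expect_equal(attr(f2, "dropped_range"), 1L)
  expect_error(filter_events(ev, curves, k_sigma = -1))
})

test_that("3-sigma clipping removes the expected Gaussian tail mass", {
  n <- 2e5
  de <- with_seed_test(9, rnorm(n, 300, 15))
  curves <- calibration_curves()
  cu <- wetrad:::roi_curve(curves, curves[[3]]$e0)
  ev <- data.frame(entry_x = 0.5, entry_y = 0.5, exit_x = 0.5, exit_y = 0.5,
                   de_keV = de, e0_MeVu = cu$e0, roi_id = 1L)
  f <- filter_events(ev, curves, k_sigma = 3)
  frac <- attr(f, "dropped_clip") / n
  expect_equal(frac, 0.0027, tolerance = 0.4)
})

test_that("noise-free reconstruction over a flat truth is exact", {
  truth <- flat_truth()
  bm <- beam_model()
  curves <- lapply(bm$energies, detector_de_curve, bm = bm, noise_frac = 0)
  plan <- plan_energy_painting(truth, c(2, 2, 10, 6), c(10, 6), curves)
  ev <- simulate_events(truth, plan, curves, n_per_pixel = 8L, seed = 4L,
                        sigma_mcs = 0)
  rec <- reconstruct_radiograph(filter_events(ev, curves), curves, plan, truth)
  expect_true(all(abs(rec$values[rec$mask] - 135) < 1e-9))
})

test_that("stage shifts stitch ROIs continuously", {
  truth <- flat_truth(120, 28L, 9L)
  bm <- beam_model()
  curves <- lapply(bm$energies, detector_de_curve, bm = bm, noise_frac = 0)
  plan <- plan_energy_painting(truth, c(2, 2, 24, 6), c(12, 6), curves)
  # pretend ROI 2 was acquired 14 mm off and shifted back by the stage
  ev <- simulate_events(truth, plan, curves, n_per_pixel = 8L, seed = 6L,
                        sigma_mcs = 0)
  sel <- ev$roi_id == 2L
  ev$exit_x[sel] <- ev$exit_x[sel] - 14
  plan$shift1[plan$roi_id == 2L] <- 14
  rec <- reconstruct_radiograph(filter_events(ev, curves), curves, plan, truth)
  v <- rec$values[rec$mask]
  expect_lt(max(abs(v - 120)), 1e-9)
})

test_that("reconstruction bias shrinks with ion statistics", {
  truth <- flat_truth(135, 10L, 10L)
  curves <- calibration_curves()
  plan <- plan_energy_painting(truth, c(1, 1, 8, 8), c(8, 8), curves)
  bias <- vapply(c(10L, 100L, 1000L), function(npp) {
    ev <- simulate_events(truth, plan, curves, n_per_pixel = npp, seed = 8L)
    f <- filter_events(ev, curves)
    cu <- wetrad:::roi_curve(curves, plan$e0[1])
    abs(median(wet_from_de(f$de_keV, cu), na.rm = TRUE) - 135)
  }, numeric(1))
  expect_true(all(diff(bias) < 0))
})

test_that("event lists round-trip through CSV", {
  truth <- flat_truth()
  curves <- calibration_curves()
  plan <- plan_energy_painting(truth, c(0, 0, 14, 9), c(14, 9), curves)
  ev <- simulate_events(truth, plan, curves, n_per_pixel = 2L, seed = 5L)
  p <- tempfile(fileext = ".csv")
  write_events_csv(ev, p)
  back <- read_events_csv(p)
  expect_equal(as.data.frame(back), as.data.frame(ev), tolerance = 1e-12)
})
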