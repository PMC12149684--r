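test_that("identity resampling onto the same grid is exact", {
  m <- bumpy_map()
  out <- resample_to_grid(m, rigid_transform2d(), m)
  expect_equal(out$values, m$values, tolerance = 1e-12)
  expect_equal(out$mask, m$mask)
})

test_that("linear structures are interpolation-exact under half-pixel shifts", {
  ramp <- outer(seq(0, 30, length.out = 21), rep(1, 15)) +
    outer(rep(1, 21), seq(5, 12, length.out = 15))
  m <- wet_map(ramp, spacing = c(1, 1), origin = c(0, 0))
  tr <- rigid_transform2d(0, c(0.5, 0), c(0, 0))
  out <- resample_to_grid(m, tr, m)
  # interior pixels: exact ramp values at the shifted positions
  want <- outer(seq(0, 30, length.out = 21) + 0.5 * 30 / 20, rep(1, 15)) +
    outer(rep(1, 21), seq(5, 12, length.out = 15))
  expect_equal(out$values[out$mask], want[out$mask], tolerance = 1e-12)
})

test_that("checkerboard means are preserved under half-pixel shifts", {
  cb <- 100 + 10 * outer(1:20, 1:20, function(i, j) (i + j) %% 2)
  m <- wet_map(cb, spacing = c(1, 1), origin = c(0, 0))
  out <- resample_to_grid(m, rigid_transform2d(0, c(0.5, 0), c(0, 0)), m)
  # bilinear at a half-pixel shift averages neighbouring cells: exactly 105
  expect_true(all(abs(out$values[out$mask] - 105) < 1e-12))
})

test_that("conservative masks invalidate pixels touched by invalid sources", {
  m <- bumpy_map()
  m$mask[4, 4] <- FALSE
  out <- resample_to_grid(m, rigid_transform2d(0, c(0.5, 0), c(0, 0)), m)
  expect_false(out$mask[3, 4])
  expect_false(out$mask[4, 4])
  expect_true(out$mask[2, 4])
})

test_that("self-registration returns the identity transform", {
  maps <- coarse_ref_maps()
  ref <- maps$common
  est <- register_wet_maps(ref, ref)
  expect_lt(abs(est$rotation_deg), 0.01)
  expect_lt(sqrt(sum(est$translation^2)), 0.01)
})

test_that("known rigid perturbations are recovered", {
  maps <- coarse_ref_maps()
  ref <- maps$common
  cg <- maps$grid
  ctr <- ref$origin + dim(ref$values) * ref$spacing / 2
  inv2d <- function(t) {
    th <- -t$rotation_deg * pi / 180
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    rigid_transform2d(-t$rotation_deg, as.vector(-R %*% t$translation),
                      t$center)
  }
  # pure shift: the benchmark displacement scale of the registration chain
  tr <- rigid_transform2d(0, c(2.0, -1.5), ctr)
  est <- register_wet_maps(resample_to_grid(ref, tr, cg), ref)
  want <- inv2d(tr)
  expect_lt(sqrt(sum((est$translation - want$translation)^2)), 0.1)
  expect_lt(abs(est$rotation_deg - want$rotation_deg), 0.1)
  # known rotation
  tr <- rigid_transform2d(3, c(0, 0), ctr)
  est <- register_wet_maps(resample_to_grid(ref, tr, cg), ref)
  want <- inv2d(tr)
  expect_lt(abs(est$rotation_deg - want$rotation_deg), 0.1)
  expect_lt(sqrt(sum((est$translation - want$translation)^2)), 0.1)
})

test_that("registration refuses maps with too little overlap", {
  a <- wet_map(matrix(100, 8, 8), spacing = c(1, 1), origin = c(0, 0))
  b <- wet_map(matrix(100, 8, 8), spacing = c(1, 1), origin = c(500, 500))
  expect_error(register_wet_maps(a, b), "overlap")
})

test_that("transforms round-trip through JSON", {
  tr <- rigid_transform2d(2.5, c(-1, 3), c(10, 20))
  p <- tempfile(fileext = ".json")
  write_transform_json(tr, p)
  back <- read_transform_json(p)
  expect_equal(back$rotation_deg, tr$rotation_deg)
  expect_equal(back$translation, tr$translation)
  expect_equal(back$center, tr$center)
})
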