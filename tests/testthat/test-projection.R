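make_rsp <- function(vals, spacing = c(1, 1, 1)) {
  rsp_volume(vals, grid_spec(dim(vals), spacing))
}

test_that("projection is the discrete RSP line integral", {
  vals <- array(0, c(100, 4, 3))
  vals[, 2, 2] <- 1
  m <- project_wet(make_rsp(vals, c(1.5, 1, 1)))
  expect_equal(m$values[2, 2], 150)
  expect_equal(m$values[1, 1], 0)
  expect_false(m$mask[1, 1])
  expect_true(m$mask[2, 2])
  expect_error(project_wet(make_rsp(vals), "oblique"), "unknown axis")
})

test_that("projection is linear and conserves mass", {
  g <- grid_spec(c(12L, 9L, 7L), c(0.7, 1.1, 1.3))
  v1 <- with_seed_test(1, array(runif(prod(g$shape)), g$shape))
  v2 <- with_seed_test(2, array(runif(prod(g$shape)), g$shape))
  a <- 0.3; b <- 1.7
  p12 <- project_wet(rsp_volume(a * v1 + b * v2, g))
  p1 <- project_wet(rsp_volume(v1, g))
  p2 <- project_wet(rsp_volume(v2, g))
  expect_equal(p12$values, a * p1$values + b * p2$values, tolerance = 1e-12)
  # sum(WET) * pixel area == sum(rsp) * voxel volume
  expect_equal(sum(p1$values) * prod(g$spacing[2:3]),
               sum(v1) * prod(g$spacing), tolerance = 1e-9)
})

test_that("external air stripping removes only boundary-connected air", {
  vals <- array(0.001, c(30, 20, 20))
  vals[8:22, 5:15, 5:15] <- 1.0     # slab body
  vals[12:18, 8:12, 8:12] <- 0.001  # enclosed pocket
  rsp <- make_rsp(vals)
  out <- strip_external_air(rsp)
  ext <- attr(out, "external_mask")
  expect_true(all(out$values[1, , ] == 0))
  # enclosed pocket keeps its (tiny) RSP and is not marked external
  expect_true(all(out$values[12:18, 8:12, 8:12] == 0.001))
  expect_false(any(ext[12:18, 8:12, 8:12]))
  # body WET unchanged by stripping except for the removed air contribution
  w0 <- project_wet(rsp)$values[10, 10]
  w1 <- project_wet(out)$values[10, 10]
  expect_equal(w1, w0 - 0.001 * (30 - 15), tolerance = 1e-9)
})

test_that("external-air voxel count matches an iterative flood-fill oracle", {
  g <- grid_spec(c(16L, 14L, 12L), c(1, 1, 1))
  vals <- with_seed_test(5, {
    v <- array(0.001, g$shape)
    # random solid blobs
    for (k in 1:4) {
      c0 <- c(sample(4:13, 1), sample(4:11, 1), sample(4:9, 1))
      v[(c0[1] - 2):(c0[1] + 2), (c0[2] - 2):(c0[2] + 2),
        (c0[3] - 2):(c0[3] + 2)] <- 1
    }
    v
  })
  rsp <- rsp_volume(vals, g)
  ext <- external_air_mask(rsp)
  # oracle: repeated 6-neighbour dilation from the boundary
  fillable <- vals < 0.05
  seen <- array(FALSE, g$shape)
  seen[1, , ] <- fillable[1, , ]; seen[g$shape[1], , ] <- fillable[g$shape[1], , ]
  seen[, 1, ] <- seen[, 1, ] | fillable[, 1, ]
  seen[, g$shape[2], ] <- seen[, g$shape[2], ] | fillable[, g$shape[2], ]
  seen[, , 1] <- seen[, , 1] | fillable[, , 1]
  seen[, , g$shape[3]] <- seen[, , g$shape[3]] | fillable[, , g$shape[3]]
  repeat {
    grown <- seen
    grown[-1, , ] <- grown[-1, , ] | seen[-g$shape[1], , ]
    grown[-g$shape[1], , ] <- grown[-g$shape[1], , ] | seen[-1, , ]
    grown[, -1, ] <- grown[, -1, ] | seen[, -g$shape[2], ]
    grown[, -g$shape[2], ] <- grown[, -g$shape[2], ] | seen[, -1, ]
    grown[, , -1] <- grown[, , -1] | seen[, , -g$shape[3]]
    grown[, , -g$shape[3]] <- grown[, , -g$shape[3]] | seen[, , -1]
    grown <- grown & fillable
    if (identical(grown, seen)) break
    seen <- grown
  }
  expect_identical(ext, seen)
})

test_that("cropping follows the ceiling convention and is idempotent", {
  m <- wet_map(matrix(1, 122, 66), spacing = c(0.98, 1.5), origin = c(0, 0))
  cr <- crop_region(m, c(36, 32, 48, 36))
  expect_equal(dim(cr$values), c(49L, 24L))
  cr2 <- crop_region(cr, c(36, 32, 48, 36))
  expect_equal(cr2$values, cr$values)
  expect_equal(cr2$origin, cr$origin)
  full <- crop_region(m, c(0, 0, 122 * 0.98, 66 * 1.5))
  expect_equal(dim(full$values), dim(m$values))
  expect_error(crop_region(m, c(100, 0, 48, 36)), "outside")
})

test_that("WET maps round-trip through CSV", {
  m <- bumpy_map()
  m$mask[2, 3] <- FALSE
  p <- tempfile(fileext = ".csv")
  write_wet_csv(m, p)
  back <- read_wet_csv(p)
  expect_equal(back$values[back$mask], m$values[m$mask])
  expect_equal(back$mask, m$mask)
  expect_equal(back$spacing, m$spacing)
})
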