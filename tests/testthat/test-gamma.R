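# Independent brute-force gamma oracle: exhaustive search over the same
# offset lattice, with its own bilinear interpolation.
gamma_brute <- function(m, ref, dose_pct, dta, upsample = 10L,
                        search_factor = 3) {
  interp <- function(map, x, y) {
    d <- dim(map$values)
    fx <- (x - map$origin[1]) / map$spacing[1] + 0.5
    fy <- (y - map$origin[2]) / map$spacing[2] + 0.5
    if (fx < 1 - 1e-9 || fx > d[1] + 1e-9 || fy < 1 - 1e-9 || fy > d[2] + 1e-9)
      return(NA_real_)
    fx <- min(max(fx, 1), d[1]); fy <- min(max(fy, 1), d[2])
    i <- min(floor(fx), d[1] - 1); j <- min(floor(fy), d[2] - 1)
    tx <- fx - i; ty <- fy - j
    corners <- rbind(c(i, j, (1 - tx) * (1 - ty)), c(i + 1, j, tx * (1 - ty)),
                     c(i, j + 1, (1 - tx) * ty), c(i + 1, j + 1, tx * ty))
    v <- 0
    for (r in seq_len(4)) {
      if (corners[r, 3] > 1e-9 && !map$mask[corners[r, 1], corners[r, 2]])
        return(NA_real_)
      v <- v + corners[r, 3] * map$values[corners[r, 1], corners[r, 2]]
    }
    v
  }
  d <- dim(ref$values)
  rad <- search_factor * dta
  step <- m$spacing / upsample
  o1 <- seq(-floor(rad / step[1]), floor(rad / step[1])) * step[1]
  o2 <- seq(-floor(rad / step[2]), floor(rad / step[2])) * step[2]
  g <- array(NA_real_, d)
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      if (!ref$mask[i, j] || !m$mask[i, j] || ref$values[i, j] <= 0) next
      x0 <- ref$origin[1] + (i - 0.5) * ref$spacing[1]
      y0 <- ref$origin[2] + (j - 0.5) * ref$spacing[2]
      wr <- ref$values[i, j]
      best <- Inf
      for (dx in o1) {
        for (dy in o2) {
          if (dx^2 + dy^2 > rad^2 + 1e-12) next
          w <- interp(m, x0 + dx, y0 + dy)
          if (is.na(w)) next
          cand <- (dx^2 + dy^2) / dta^2 +
            (w - wr)^2 / (dose_pct / 100 * wr)^2
          if (cand < best) best <- cand
        }
      }
      g[i, j] <- sqrt(best)
    }
  }
  g
}

test_that("gamma of a map against itself is exactly zero", {
  m <- bumpy_map()
  g <- gamma_map(m, m, gamma_criteria(0.7, 1), n_regions = 4L)
  expect_true(all(g$values[g$mask] == 0))
  expect_equal(g$pass_rate, 100)
})

test_that("a uniform offset at the dose criterion sits on the pass boundary", {
  ref <- wet_map(matrix(135, 9, 9), spacing = c(1, 1))
  m <- wet_map(matrix(135 * 1.007, 9, 9), spacing = c(1, 1))
  g <- gamma_map(m, ref, gamma_criteria(0.7, 1), n_regions = 4L)
  expect_true(all(abs(g$values[g$mask] - 1) < 1e-9))
  expect_equal(g$pass_rate, 100)
})

test_that("gamma equals the exhaustive brute-force search", {
  for (s in c(1, 2)) {
    ref <- with_seed_test(s, wet_map(matrix(120 + 10 * runif(25), 5, 5),
                                     spacing = c(1, 1)))
    m <- with_seed_test(s + 100,
                        wet_map(ref$values * (1 + rnorm(25, 0, 0.01)),
                                spacing = c(1, 1)))
    g <- gamma_map(m, ref, gamma_criteria(0.7, 1), n_regions = 4L)
    gb <- gamma_brute(m, ref, 0.7, 1)
    expect_lt(max(abs(g$values - gb), na.rm = TRUE), 1e-6)
  }
  # and on a 7 x 7 map with an invalid pixel
  ref <- with_seed_test(7, wet_map(matrix(130 + 8 * runif(49), 7, 7),
                                   spacing = c(1, 1)))
  m <- with_seed_test(8, wet_map(ref$values * (1 + rnorm(49, 0, 0.015)),
                                 spacing = c(1, 1)))
  m$mask[3, 4] <- FALSE
  g <- gamma_map(m, ref, gamma_criteria(0.7, 1), n_regions = 4L)
  gb <- gamma_brute(m, ref, 0.7, 1)
  expect_equal(is.na(as.vector(g$values)), is.na(as.vector(gb)))
  expect_lt(max(abs(g$values - gb), na.rm = TRUE), 1e-6)
})

test_that("loosening the criteria never fails a passing pixel", {
  ref <- with_seed_test(31, wet_map(matrix(120 + 30 * runif(200), 20, 10),
                                    spacing = c(1, 1)))
  m <- with_seed_test(32, wet_map(ref$values * (1 + rnorm(200, 0.005, 0.012)),
                                  spacing = c(1, 1)))
  g1 <- gamma_map(m, ref, gamma_criteria(0.7, 1), n_regions = 4L)
  g2 <- gamma_map(m, ref, gamma_criteria(2, 2), n_regions = 4L)
  g3 <- gamma_map(m, ref, gamma_criteria(3, 3), n_regions = 4L)
  p1 <- g1$values <= 1; p2 <- g2$values <= 1; p3 <- g3$values <= 1
  expect_true(all(p2[p1], na.rm = TRUE))
  expect_true(all(p3[p2], na.rm = TRUE))
  expect_lte(g1$pass_rate, g2$pass_rate)
  expect_lte(g2$pass_rate, g3$pass_rate)
})
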