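#' Plan energy painting over a tiled region
#'
#' Tiles the imaged region into ROIs and assigns each ROI the lowest beam
#' energy whose calibration window contains the ROI's expected WET interval
#' (the 2nd-98th percentile of the prior map inside the ROI). Keeping the
#' residual depth small keeps the steep rising edge of the Bragg curve in
#' the detector, which is where the dE-to-WET sensitivity is best.
#'
#' @param prior a `wet_map` covering the region (e.g. a projected SECT map).
#' @param region_mm region rectangle `c(min1, min2, width, height)` in mm.
#' @param roi_mm ROI tile size in mm (default 12 x 12).
#' @param curves list of `calibration_curve`s, one per available energy.
#' @return an `roi_plan` data.frame with one row per ROI: rectangle, assigned
#'   energy and stage shift (zero by default).
#' @export
plan_energy_painting <- function(prior, region_mm, roi_mm = c(12, 12),
                                 curves = calibration_curves()) {
  stopifnot(length(curves) >= 1)
  n1 <- region_mm[3] / roi_mm[1]
  n2 <- region_mm[4] / roi_mm[2]
  if (abs(n1 - round(n1)) > 1e-6 || abs(n2 - round(n2)) > 1e-6) {
    stop("ROI size must tile the region exactly")
  }
  n1 <- round(n1); n2 <- round(n2)
  sub <- crop_region(prior, region_mm)
  d <- dim(sub$values)
  # near-equal blocks of whole pixels (the region is generally not an
  # integer number of pixels wide, so tiles are defined in index space)
  b1 <- ceiling(seq_len(d[1]) / d[1] * n1)
  b2 <- ceiling(seq_len(d[2]) / d[2] * n2)
  e0s <- vapply(curves, function(cu) cu$e0, numeric(1))
  ord <- order(e0s)
  plan <- data.frame(roi_id = seq_len(n1 * n2),
                     min1 = NA_real_, min2 = NA_real_,
                     width = NA_real_, height = NA_real_,
                     e0 = NA_real_, shift1 = 0, shift2 = 0,
                     n_px = NA_integer_, wet_lo = NA_real_, wet_hi = NA_real_)
  failed <- integer(0)
  k <- 0L
  for (j in seq_len(n2)) {
    for (i in seq_len(n1)) {
      k <- k + 1L
      ii <- which(b1 == i)
      jj <- which(b2 == j)
      plan$min1[k] <- sub$origin[1] + (ii[1] - 1) * sub$spacing[1]
      plan$min2[k] <- sub$origin[2] + (jj[1] - 1) * sub$spacing[2]
      plan$width[k] <- length(ii) * sub$spacing[1]
      plan$height[k] <- length(jj) * sub$spacing[2]
      plan$n_px[k] <- length(ii) * length(jj)
      v <- sub$values[ii, jj][sub$mask[ii, jj]]
      if (!length(v)) { failed <- c(failed, k); next }
      iv <- quantile(v, c(0.02, 0.98), names = FALSE)
      plan$wet_lo[k] <- iv[1]; plan$wet_hi[k] <- iv[2]
      hit <- NA
      for (ci in ord) {
        w <- curves[[ci]]$window
        if (iv[1] >= w[1] && iv[2] <= w[2]) { hit <- ci; break }
      }
      if (is.na(hit)) failed <- c(failed, k) else plan$e0[k] <- curves[[hit]]$e0
    }
  }
  if (length(failed)) {
    stop("planning error: no calibration window contains the WET interval of ROI(s) ",
         paste(failed, collapse = ", "))
  }
  class(plan) <- c("roi_plan", "data.frame")
  plan
}

roi_curve <- function(curves, e0) {
  e0s <- vapply(curves, function(cu) cu$e0, numeric(1))
  k <- which(abs(e0s - e0) < 1e-6)
  if (!length(k)) stop("no calibration curve for energy ", e0)
  curves[[k[1]]]
}

#' Simulate single-ion radiography events
#'
#' Per ion: the entry position is uniform over its ROI, the exit position
#' adds a Gaussian lateral displacement (multiple Coulomb scattering), the
#' true WET is read bilinearly from the truth map at the exit position, and
#' the recorded energy deposition is the calibration-curve mean at that WET
#' plus fractional Gaussian straggling noise. Ions whose WET falls outside
#' their ROI's calibration window get a linearly extrapolated (out-of-range)
#' dE so that downstream filtering can remove them.
#'
#' @param truth a `wet_map` with the ground-truth WET.
#' @param plan an `roi_plan`.
#' @param curves list of `calibration_curve`s.
#' @param n_per_pixel ions per truth pixel of each ROI (>= 1).
#' @param seed integer seed; each ROI uses an independent substream.
#' @param sigma_mcs lateral scattering sigma in mm.
#' @return an `event_list` data.frame with columns `entry_x`, `entry_y`,
#'   `exit_x`, `exit_y`, `de_keV`, `e0_MeVu`, `roi_id`.
#' @export
simulate_events <- function(truth, plan, curves, n_per_pixel = 20L,
                            seed = 1L, sigma_mcs = 1.0) {
  stopifnot(n_per_pixel >= 1)
  out <- vector("list", nrow(plan))
  for (k in seq_len(nrow(plan))) {
    roi <- plan[k, ]
    npx <- if (!is.null(roi$n_px) && !is.na(roi$n_px)) roi$n_px else {
      prod(dim(crop_region(truth, c(roi$min1, roi$min2, roi$width,
                                    roi$height))$values))
    }
    n <- as.integer(n_per_pixel * npx)
    cu <- roi_curve(curves, roi$e0)
    out[[k]] <- with_seed(child_seed(seed, roi$roi_id), {
      ex <- runif(n, roi$min1, roi$min1 + roi$width)
      ey <- runif(n, roi$min2, roi$min2 + roi$height)
      xx <- ex + rnorm(n, 0, sigma_mcs)
      xy <- ey + rnorm(n, 0, sigma_mcs)
      wet <- sample_map_bilinear(truth, cbind(xx, xy))
      de0 <- de_with_extrapolation(cu, wet)
      de0[is.na(wet)] <- 0
      de <- pmax(de0 * (1 + rnorm(n, 0, cu$noise_frac)), 0)
      data.frame(entry_x = ex, entry_y = ey, exit_x = xx, exit_y = xy,
                 de_keV = de, e0_MeVu = roi$e0, roi_id = roi$roi_id)
    })
  }
  ev <- do.call(rbind, out)
  class(ev) <- c("event_list", "data.frame")
  ev
}

#' Filter radiography events
#'
#' Two passes: (1) drop events whose energy deposition lies outside their
#' curve's sampled dE range (out-of-window ions); (2) per-pixel k-sigma
#' clipping of the remaining dE values. Counts removed by each rule are
#' attached as attributes `dropped_range` and `dropped_clip`.
#'
#' @param events an `event_list`.
#' @param curves list of `calibration_curve`s.
#' @param k_sigma clipping factor (> 0, default 3).
#' @param spacing pixel spacing used for the per-pixel grouping.
#' @param origin grouping-grid origin; default the floor of the exit extent.
#' @return the filtered `event_list`.
#' @export
filter_events <- function(events, curves, k_sigma = 3,
                          spacing = c(0.98, 1.5), origin = NULL) {
  stopifnot(k_sigma > 0)
  e0s <- unique(events$e0_MeVu)
  in_range <- rep(FALSE, nrow(events))
  for (e0 in e0s) {
    cu <- roi_curve(curves, e0)
    sel <- events$e0_MeVu == e0
    in_range[sel] <- events$de_keV[sel] >= min(cu$de) &
      events$de_keV[sel] <= max(cu$de)
  }
  dropped_range <- sum(!in_range)
  ev <- events[in_range, , drop = FALSE]

  if (is.null(origin)) origin <- floor(c(min(ev$exit_x), min(ev$exit_y)))
  px <- floor((ev$exit_x - origin[1]) / spacing[1])
  py <- floor((ev$exit_y - origin[2]) / spacing[2])
  gid <- paste(px, py, sep = ",")
  mu <- tapply(ev$de_keV, gid, mean)
  sg <- tapply(ev$de_keV, gid, sd)
  m <- mu[gid]
  s <- sg[gid]
  keep <- is.na(s) | s == 0 | abs(ev$de_keV - m) <= k_sigma * s
  dropped_clip <- sum(!keep)
  out <- ev[keep, , drop = FALSE]
  class(out) <- c("event_list", "data.frame")
  attr(out, "dropped_range") <- dropped_range
  attr(out, "dropped_clip") <- dropped_clip
  out
}

#' Reconstruct a WET map from filtered events
#'
#' Each ion's WET estimate (monotone inverse of its ROI's calibration curve)
#' is binned at its exit position shifted by the ROI's stage shift; the
#' per-pixel estimate is the median ion WET. Pixels with fewer than
#' `min_ions` contributing ions are masked invalid. The per-pixel ion count
#' map is attached as attribute `counts`.
#'
#' @param events a filtered `event_list`.
#' @param curves list of `calibration_curve`s.
#' @param plan the `roi_plan` (for stage shifts).
#' @param grid a `map_grid` or `wet_map` defining the output pixel grid.
#' @param min_ions minimum ions per valid pixel (default 5).
#' @return a `wet_map` with provenance `"arad"`.
#' @export
reconstruct_radiograph <- function(events, curves, plan, grid, min_ions = 5L) {
  if (inherits(grid, "wet_map")) {
    grid <- map_grid(dim(grid$values), grid$spacing, grid$origin)
  }
  wet <- rep(NA_real_, nrow(events))
  for (e0 in unique(events$e0_MeVu)) {
    sel <- events$e0_MeVu == e0
    wet[sel] <- wet_from_de(events$de_keV[sel], roi_curve(curves, e0))
  }
  sh <- plan[match(events$roi_id, plan$roi_id), c("shift1", "shift2")]
  x <- events$exit_x + sh$shift1
  y <- events$exit_y + sh$shift2
  i <- floor((x - grid$origin[1]) / grid$spacing[1]) + 1L
  j <- floor((y - grid$origin[2]) / grid$spacing[2]) + 1L
  ok <- !is.na(wet) & i >= 1L & i <= grid$shape[1] & j >= 1L & j <= grid$shape[2]
  if (!any(ok)) stop("empty-map error: no ions fall on the output grid")
  pid <- i[ok] + (j[ok] - 1L) * grid$shape[1]
  med <- tapply(wet[ok], pid, median)
  cnt <- tabulate(pid, nbins = prod(grid$shape))
  vals <- numeric(prod(grid$shape))
  vals[as.integer(names(med))] <- med
  mask <- cnt >= min_ions
  vals[!mask] <- 0
  dim(vals) <- grid$shape
  dim(mask) <- grid$shape
  counts <- cnt
  dim(counts) <- grid$shape
  out <- wet_map(pmax(vals, 0), spacing = grid$spacing, origin = grid$origin,
                 mask = mask, provenance = "arad")
  attr(out, "counts") <- counts
  out
}

#' Write / read event lists as CSV
#'
#' @param events an `event_list`.
#' @param path file path.
#' @export
write_events_csv <- function(events, path) {
  write.csv(as.data.frame(events), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  ev <- read.csv(path)
  class(ev) <- c("event_list", "data.frame")
  ev
}
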