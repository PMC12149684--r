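#' Homogeneous-slab WET accuracy benchmark
#'
#' Simulates an energy-painted radiograph of homogeneous water-equivalent
#' slabs and reports the relative accuracy of the reconstructed WET. Each
#' slab is built as a voxel phantom, projected to its true WET map, assigned
#' the planned beam energy, imaged with `n_ions` ions under the default
#' noise model, and reconstructed as the median per-ion WET estimate. The
#' benchmark MAPE is the mean absolute percentage error across slabs.
#'
#' @param wets slab water-equivalent thicknesses in mm.
#' @param n_ions ions per slab.
#' @param seed integer seed (one substream per slab).
#' @param bm a `beam_model`.
#' @return list with `per_slab` (truth, estimate, error in percent) and
#'   `mape` (percent).
#' @export
slab_benchmark <- function(wets = c(95, 115, 135, 155, 175), n_ions = 1e4,
                           seed = 42L, bm = beam_model()) {
  curves <- calibration_curves(bm)
  grid <- grid_spec(c(420L, 40L, 40L), c(0.5, 0.5, 0.5))
  rows <- lapply(seq_along(wets), function(k) {
    slab <- build_slab_phantom(wets[k], rsp = 1.0, grid = grid)
    m <- crop_region(project_wet(assign_rsp(slab)), c(4, 4, 12, 12))
    # painted region inset by one pixel so every scattered ion still lands
    # on the interpolable part of the truth map
    plan <- plan_energy_painting(m, c(5, 5, 10, 10), c(10, 10), curves)
    npp <- max(1L, round(n_ions / plan$n_px[1]))
    ev <- simulate_events(m, plan, curves, n_per_pixel = npp,
                          seed = child_seed(seed, k))
    fev <- filter_events(ev, curves)
    cu <- roi_curve(curves, plan$e0[1])
    est <- median(wet_from_de(fev$de_keV, cu), na.rm = TRUE)
    truth <- mean(m$values[m$mask])
    data.frame(wet_nominal = wets[k], wet_true = truth, e0 = plan$e0[1],
               n_ions = nrow(ev), estimate = est,
               error_pct = 100 * abs(est - truth) / truth)
  })
  per_slab <- do.call(rbind, rows)
  list(per_slab = per_slab, mape = mean(per_slab$error_pct))
}
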