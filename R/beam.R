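#' Helium beam model
#'
#' A power-law range-energy closure `R = alpha * E^q` (mm water) plus the
#' fixed water-equivalent thickness of the downstream degrader/detector
#' stack. The default five initial energies span 146.84 to 188.07 MeV/u with
#' equal spacing in range, so their calibration windows jointly cover the
#' 90-180 mm WET interval relevant for base-of-skull imaging.
#'
#' @param alpha range coefficient, mm/(MeV/u)^q.
#' @param q range exponent (dimensionless, between 1 and 2.2).
#' @param energies strictly increasing initial beam energies in MeV/u.
#' @param focus_fwhm beam focus FWHM in mm.
#' @param stack_wet water-equivalent thickness of degrader plus upstream
#'   detector material, mm.
#' @return a `beam_model`.
#' @export
beam_model <- function(alpha = 0.0222, q = 1.77, energies = NULL,
                       focus_fwhm = 10.7, stack_wet = 15) {
  stopifnot(alpha > 0, q > 1, q < 2.2)
  if (is.null(energies)) energies <- default_energies(alpha, q)
  if (any(diff(energies) <= 0)) stop("energies must be strictly increasing")
  structure(list(alpha = alpha, q = q, energies = energies,
                 focus_fwhm = focus_fwhm, stack_wet = stack_wet),
            class = "beam_model")
}

#' @rdname beam_model
#' @details `default_energies()` places five energies between the fixed
#'   endpoints so that their ranges in water are equally spaced, which makes
#'   the calibration windows overlap evenly.
#' @export
default_energies <- function(alpha = 0.0222, q = 1.77,
                             e_lo = 146.84, e_hi = 188.07, n = 5L) {
  r <- seq(alpha * e_lo^q, alpha * e_hi^q, length.out = n)
  e <- (r / alpha)^(1 / q)
  e[1] <- e_lo
  e[n] <- e_hi
  e
}

#' Range in water from initial energy
#'
#' `R = alpha * E0^q`; with the defaults, R(150 MeV/u) is about 158 mm.
#'
#' @param e0 initial energy in MeV/u (> 0).
#' @param bm a `beam_model`.
#' @return range in mm of water.
#' @export
range_from_energy <- function(e0, bm = beam_model()) {
  stopifnot(all(e0 > 0))
  bm$alpha * e0^bm$q
}

# Mean Bragg-curve energy deposition (arbitrary keV scale) in a thin silicon
# detector at residual water range r, smoothed by Gaussian range straggling.
# Below r = 0 the ions have stopped upstream and deposit nothing.
bragg_de <- function(r, q, sigma_r = 1.5, k = NULL) {
  p <- 1 / q - 1 # stopping power ~ r^p near the end of range
  if (is.null(k)) k <- 150 / (50.5^p)
  u <- seq(-5, 5, by = 0.25) * sigma_r
  w <- dnorm(u, sd = sigma_r)
  w <- w / sum(w)
  s <- numeric(length(r))
  for (t in seq_along(u)) {
    rt <- r + u[t]
    s <- s + w[t] * ifelse(rt > 0, (rt + 0.5)^p, 0)
  }
  k * s
}

#' Energy-deposition calibration curve for one beam energy
#'
#' Expected energy deposition in the thin downstream detector as a function
#' of the traversed WET, evaluated on `wet_grid` with a smoothed
#' one-over-square-root Bragg shape at the residual depth
#' `R(e0) - stack_wet - wet` and range straggling `sigma_r`. The valid
#' window is the maximal WET interval on which the curve is strictly
#' increasing with positive residual depth.
#'
#' @param e0 initial energy, MeV/u.
#' @param bm a `beam_model`.
#' @param wet_grid increasing WET sample points (mm); default spans residual
#'   depths from 75 down to 5 mm.
#' @param sigma_r range straggling sigma in mm.
#' @param noise_frac fractional Gaussian energy-deposition noise per ion.
#' @return a `calibration_curve`: sampled `(wet, de)` table, valid `window`,
#'   and monotone forward/inverse interpolators.
#' @export
detector_de_curve <- function(e0, bm = beam_model(), wet_grid = NULL,
                              sigma_r = 1.5, noise_frac = 0.05) {
  R <- range_from_energy(e0, bm)
  if (R - bm$stack_wet < 10) {
    stop("beam energy outside model validity: ions stop in the stack")
  }
  if (is.null(wet_grid)) {
    # the smoothed Bragg edge peaks near a residual depth of 3.8 mm; stop
    # the declared window at 5 mm so it stays strictly monotone at any
    # sampling density
    wet_grid <- seq(max(R - bm$stack_wet - 75, 1), R - bm$stack_wet - 5,
                    by = 0.5)
  }
  if (any(diff(wet_grid) <= 0)) stop("wet_grid must be increasing")
  d <- R - bm$stack_wet - wet_grid
  de <- bragg_de(d, bm$q, sigma_r)
  de[d <= 0] <- NA_real_ # ions stop upstream of the detector
  ok <- which(!is.na(de))
  inc <- diff(de[ok]) > 0
  cut <- if (all(inc)) length(ok) else min(which(!inc))
  keep <- ok[seq_len(cut)]
  wet <- wet_grid[keep]
  dev <- de[keep]
  if (length(wet) < 2) stop("no strictly increasing window for this energy")
  structure(list(e0 = e0, wet = wet, de = dev,
                 window = c(wet[1], wet[length(wet)]),
                 noise_frac = noise_frac,
                 fwd = approxfun(wet, dev, rule = 2),
                 inv = approxfun(dev, wet)),
            class = "calibration_curve")
}

#' @rdname detector_de_curve
#' @param curves optional list of `calibration_curve`s; default builds one
#'   per beam-model energy.
#' @export
calibration_curves <- function(bm = beam_model(), curves = NULL, ...) {
  if (!is.null(curves)) return(curves)
  lapply(bm$energies, detector_de_curve, bm = bm, ...)
}

# Linear extrapolation of the expected dE outside the calibration window,
# used when simulating ions whose true WET escapes their ROI's window; such
# events carry out-of-range dE and are removed by filter_events().
de_with_extrapolation <- function(curve, wet) {
  de <- curve$fwd(wet)
  n <- length(curve$wet)
  slope_lo <- (curve$de[2] - curve$de[1]) / (curve$wet[2] - curve$wet[1])
  slope_hi <- (curve$de[n] - curve$de[n - 1]) / (curve$wet[n] - curve$wet[n - 1])
  lo <- !is.na(wet) & wet < curve$wet[1]
  hi <- !is.na(wet) & wet > curve$wet[n]
  de[lo] <- curve$de[1] + slope_lo * (wet[lo] - curve$wet[1])
  de[hi] <- curve$de[n] + slope_hi * (wet[hi] - curve$wet[n])
  pmax(de, 0)
}

#' Invert a calibration curve
#'
#' Monotone piecewise-linear inverse of the sampled dE-WET table. Energy
#' depositions outside the curve's dE range return `NA` (the invalid
#' marker).
#'
#' @param de energy deposition in keV.
#' @param curve a `calibration_curve`.
#' @return WET in mm, or `NA` where `de` is out of range.
#' @export
wet_from_de <- function(de, curve) {
  curve$inv(de)
}

#' Write / read calibration curves as CSV
#'
#' One file per energy with columns `wet_mm`, `de_keV`.
#' @param curve a `calibration_curve`.
#' @param path file path.
#' @export
write_curve_csv <- function(curve, path) {
  write.csv(data.frame(wet_mm = curve$wet, de_keV = curve$de), path,
            row.names = FALSE)
  invisible(path)
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("calibration_curve: e0 = %.2f MeV/u, window [%.1f, %.1f] mm, dE [%.1f, %.1f] keV\n",
              x$e0, x$window[1], x$window[2], min(x$de), max(x$de)))
  invisible(x)
}
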