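#' Gamma analysis criteria
#'
#' @param dose_pct WET tolerance in percent of the local reference value
#'   (local normalization). The default 0.7 corresponds to a 1 mm range
#'   tolerance at a mean WET of 135 mm.
#' @param dta_mm distance-to-agreement tolerance in mm.
#' @return a `gamma_criteria`.
#' @export
gamma_criteria <- function(dose_pct = 0.7, dta_mm = 1.0) {
  stopifnot(dose_pct > 0, dta_mm > 0)
  structure(list(dose_pct = dose_pct, dta_mm = dta_mm,
                 normalization = "local"),
            class = "gamma_criteria")
}

#' Local gamma analysis of two WET maps
#'
#' For each valid reference pixel p,
#' `gamma(p) = min_r sqrt(|r - p|^2 / dta^2 + (W(r) - W_ref(p))^2 / (tol * W_ref(p))^2)`
#' with `tol = dose_pct / 100` (local normalization), the minimum taken over
#' displaced positions within a search radius of 3 x dta. The evaluated map
#' W is sampled bilinearly on a 10x upsampled offset lattice. The pass rate
#' is the fraction of valid pixels with gamma <= 1; its standard error uses
#' the same subregion scheme as the MAPE/RMSPE uncertainties.
#'
#' @param m evaluated `wet_map`.
#' @param ref reference `wet_map` on the same grid.
#' @param criteria a `gamma_criteria`.
#' @param upsample offset lattice refinement factor (default 10).
#' @param search_factor search radius in units of `dta_mm` (default 3).
#' @param n_regions subregions for the pass-rate standard error.
#' @return a `gamma_map`: per-pixel gamma values, `pass_rate` (percent),
#'   `pass_rate_se` and the validity mask.
#' @export
gamma_map <- function(m, ref, criteria = gamma_criteria(), upsample = 10L,
                      search_factor = 3, n_regions = 42L) {
  if (!same_map_grid(m, ref)) stop("grid mismatch between map and reference")
  mask <- m$mask & ref$mask & ref$values > 0
  tol <- criteria$dose_pct / 100
  dta <- criteria$dta_mm
  rad <- search_factor * dta

  step <- m$spacing / upsample
  off1 <- seq(-floor(rad / step[1]), floor(rad / step[1])) * step[1]
  off2 <- seq(-floor(rad / step[2]), floor(rad / step[2])) * step[2]
  offs <- expand.grid(d1 = off1, d2 = off2)
  offs <- offs[offs$d1^2 + offs$d2^2 <= rad^2 + 1e-12, ]
  # evaluate nearest offsets first so the running minimum converges quickly
  offs <- offs[order(offs$d1^2 + offs$d2^2), ]

  d <- dim(ref$values)
  cx <- map_coords(ref, 1)
  cy <- map_coords(ref, 2)
  pts <- cbind(rep(cx, times = d[2]), rep(cy, each = d[1]))
  wref <- as.vector(ref$values)
  denom <- (tol * wref)^2
  g2 <- rep(Inf, length(wref))
  act <- as.vector(mask)
  # zero-offset candidate taken directly from the pixel values (no
  # interpolation), so identical maps give gamma exactly 0
  direct <- act & as.vector(m$mask)
  g2[direct] <- (as.vector(m$values)[direct] - wref[direct])^2 / denom[direct]
  for (k in seq_len(nrow(offs))) {
    dist2 <- (offs$d1[k]^2 + offs$d2[k]^2) / dta^2
    live <- act & (g2 > dist2) # offsets farther than the current minimum cannot help
    if (!any(live)) next
    w <- sample_map_bilinear(m, cbind(pts[live, 1] + offs$d1[k],
                                      pts[live, 2] + offs$d2[k]))
    cand <- dist2 + (w - wref[live])^2 / denom[live]
    upd <- !is.na(cand) & cand < g2[live]
    idx <- which(live)[upd]
    g2[idx] <- cand[upd]
    if (dist2 > max(g2[act], na.rm = TRUE)) break
  }
  g <- sqrt(g2)
  g[!act] <- NA_real_
  computed <- act & is.finite(g)
  dim(g) <- d
  dim(computed) <- d

  passes <- g <= 1 & computed
  pass_rate <- 100 * sum(passes, na.rm = TRUE) / sum(computed)
  pd <- structure(list(values = array(as.numeric(passes), d), mask = computed,
                       spacing = ref$spacing, origin = ref$origin),
                  class = "diff_map")
  se <- tryCatch({
    rid <- region_ids(pd, n_regions)
    rates <- tapply(as.vector(passes)[as.vector(computed)],
                    as.vector(rid)[as.vector(computed)], mean)
    100 * sd(rates) / sqrt(length(rates))
  }, error = function(e) NA_real_)

  structure(list(values = g, mask = computed, pass_rate = pass_rate,
                 pass_rate_se = se, criteria = criteria,
                 spacing = ref$spacing, origin = ref$origin),
            class = "gamma_map")
}

#' @export
print.gamma_map <- function(x, ...) {
  cat(sprintf("gamma_map (%g%%, %g mm, local): pass rate %.1f%% +/- %.1f%% over %d px\n",
              x$criteria$dose_pct, x$criteria$dta_mm, x$pass_rate,
              x$pass_rate_se, sum(x$mask)))
  invisible(x)
}
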