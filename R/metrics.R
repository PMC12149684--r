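#' Relative WET difference map
#'
#' Per-pixel relative difference in percent,
#' `100 * (WET - WET_ref) / WET_ref`, over the intersection of the two
#' validity masks. Pixels whose reference WET is below 1 mm are masked out
#' to avoid division blow-up.
#'
#' @param m evaluated `wet_map`.
#' @param ref reference `wet_map` on the same pixel grid.
#' @return a `diff_map`: percent values plus validity mask.
#' @export
relative_diff_map <- function(m, ref) {
  if (!same_map_grid(m, ref)) stop("grid mismatch between map and reference")
  mask <- m$mask & ref$mask & ref$values >= 1
  vals <- array(NA_real_, dim(m$values))
  vals[mask] <- 100 * (m$values[mask] - ref$values[mask]) / ref$values[mask]
  structure(list(values = vals, mask = mask, spacing = m$spacing,
                 origin = m$origin, provenance = m$provenance),
            class = "diff_map")
}

#' @rdname relative_diff_map
#' @param values percent values (matrix or vector).
#' @param mask optional validity mask.
#' @param spacing,origin pixel geometry.
#' @export
diff_map <- function(values, mask = NULL, spacing = c(0.98, 1.5),
                     origin = c(0, 0)) {
  values <- as.matrix(values)
  if (is.null(mask)) mask <- !is.na(values)
  structure(list(values = values, mask = as.matrix(mask), spacing = spacing,
                 origin = origin, provenance = "manual"),
            class = "diff_map")
}

#' Mean absolute percentage error of a difference map
#'
#' @param d a `diff_map`.
#' @return MAPE in percent.
#' @export
mape <- function(d) {
  v <- d$values[d$mask]
  if (!length(v)) stop("empty mask: no valid pixels")
  mean(abs(v))
}

#' Root-mean-square percentage error of a difference map
#'
#' @param d a `diff_map`.
#' @return RMSPE in percent. Always >= the MAPE of the same map.
#' @export
rmspe <- function(d) {
  v <- d$values[d$mask]
  if (!length(v)) stop("empty mask: no valid pixels")
  sqrt(mean(v^2))
}

# Tile a map's pixel index space into approximately n_regions rectangular
# tiles (default 42 as a 7 x 6 layout); partial tiles at the borders are
# absorbed by equal-width index cuts.
region_ids <- function(d, n_regions) {
  dm <- dim(d$values)
  fac <- best_tiling(n_regions, dm)
  ri <- ceiling(seq_len(dm[1]) / dm[1] * fac[1])
  ci <- ceiling(seq_len(dm[2]) / dm[2] * fac[2])
  outer(ri, (ci - 1) * fac[1], "+")
}

best_tiling <- function(n, dm) {
  divs <- which(n %% seq_len(n) == 0)
  aspect <- dm[1] / dm[2]
  sc <- vapply(divs, function(a) abs(log((a / (n / a)) / aspect)), numeric(1))
  a <- divs[which.min(sc)]
  c(a, n / a)
}

#' Subregion-based standard errors for MAPE and RMSPE
#'
#' Divides the map into `n_regions` equal tiles (42 by default, laid out to
#' match the map aspect, e.g. 7 x 6 on the default imaged region), computes
#' MAPE and RMSPE per tile, and reports the standard error of the mean
#' across tiles as the uncertainty of the whole-image values. Tiles with no
#' valid pixels are excluded with a warning.
#'
#' @param d a `diff_map`.
#' @param n_regions number of subregions (>= 2).
#' @return list with `mape_se`, `rmspe_se`, `n_used` and the per-region
#'   table.
#' @export
subregion_uncertainty <- function(d, n_regions = 42L) {
  stopifnot(n_regions >= 2)
  rid <- region_ids(d, n_regions)
  per <- lapply(sort(unique(as.vector(rid))), function(r) {
    v <- d$values[d$mask & rid == r]
    if (!length(v)) return(NULL)
    data.frame(region = r, mape = mean(abs(v)), rmspe = sqrt(mean(v^2)),
               n_px = length(v))
  })
  empty <- sum(vapply(per, is.null, logical(1)))
  if (empty > 0) {
    warning(sprintf("%d subregion(s) with empty mask excluded", empty))
  }
  per <- do.call(rbind, per)
  n <- nrow(per)
  list(mape_se = sd(per$mape) / sqrt(n),
       rmspe_se = sd(per$rmspe) / sqrt(n),
       n_used = n, per_region = per)
}

#' Folded-normal MAPE and RMSPE implied by a Gaussian error model
#'
#' If the per-pixel relative differences are N(mu, sigma), the MAPE is the
#' folded-normal mean
#' `sigma * sqrt(2/pi) * exp(-mu^2 / (2 sigma^2)) + mu * erf(mu / (sigma sqrt(2)))`
#' and the RMSPE is `sqrt(mu^2 + sigma^2)`. Used as a consistency check
#' between a distribution's standard deviation and its MAPE/RMSPE summary.
#'
#' @param mu mean of the relative-difference distribution (percent).
#' @param sigma standard deviation (percent, > 0).
#' @return list with `mape` and `rmspe` (percent).
#' @export
folded_normal_stats <- function(mu, sigma) {
  stopifnot(sigma > 0)
  erf_term <- 2 * stats::pnorm(mu / sigma) - 1 # erf(mu / (sigma * sqrt(2)))
  list(mape = sigma * sqrt(2 / pi) * exp(-mu^2 / (2 * sigma^2)) + mu * erf_term,
       rmspe = sqrt(mu^2 + sigma^2))
}

#' Distribution summary of a difference map
#'
#' @param d a `diff_map` with at least two valid pixels.
#' @param breaks histogram break count or vector (default 40 equal bins over
#'   the data range).
#' @return list with `std`, `median`, `q1`, `q3` and a histogram table
#'   (`bin_left`, `bin_right`, `count`).
#' @export
distribution_summary <- function(d, breaks = 40L) {
  v <- d$values[d$mask]
  if (length(v) < 2) stop("need at least 2 valid pixels")
  if (length(breaks) == 1L) {
    breaks <- seq(min(v), max(v), length.out = breaks + 1L)
    breaks[length(breaks)] <- breaks[length(breaks)] + 1e-9
  }
  cnt <- tabulate(findInterval(v, breaks, rightmost.closed = TRUE),
                  nbins = length(breaks) - 1L)
  q <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
  list(std = sd(v), median = q[2], q1 = q[1], q3 = q[3],
       hist = data.frame(bin_left = head(breaks, -1L),
                         bin_right = tail(breaks, -1L), count = cnt))
}
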