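#' Material abundance maps along pixel channels
#'
#' For every material, the percentage of in-phantom voxels of that material
#' in each pixel channel (the column of voxels integrated to form one WET
#' pixel). Only voxels inside the phantom count, so the per-pixel
#' percentages sum to 100 over materials wherever the channel crosses the
#' phantom.
#'
#' @param lv a `label_volume`.
#' @param axis projection axis name or index.
#' @param phantom_mask logical array marking in-phantom voxels; by default
#'   everything that is not boundary-connected external air.
#' @return an `abundance_maps` object: one percentage matrix per material
#'   plus the channel validity mask and pixel geometry.
#' @export
material_abundance_maps <- function(lv, axis = "sagittal",
                                    phantom_mask = NULL) {
  k <- axis_index(lv$grid, axis)
  if (is.null(phantom_mask)) {
    phantom_mask <- !external_air_mask(assign_rsp(lv))
  }
  perm <- c(k, setdiff(1:3, k))
  lab <- if (k == 1L) lv$labels else aperm(lv$labels, perm)
  pm <- if (k == 1L) phantom_mask else aperm(phantom_mask, perm)
  d <- dim(lab)
  labm <- matrix(lab, nrow = d[1])
  pmm <- matrix(pm, nrow = d[1])
  denom <- colSums(pmm)
  maps <- lapply(lv$table$id, function(id) {
    num <- colSums((labm == id) & pmm)
    v <- ifelse(denom > 0, 100 * num / denom, NA_real_)
    dim(v) <- d[2:3]
    v
  })
  names(maps) <- lv$table$name
  mask <- denom > 0
  dim(mask) <- d[2:3]
  keep <- setdiff(1:3, k)
  structure(list(maps = maps, mask = mask,
                 spacing = lv$grid$spacing[keep],
                 origin = lv$grid$origin[keep],
                 axis_names = lv$grid$axis_names[keep]),
            class = "abundance_maps")
}

#' Resample abundance maps onto a WET-map pixel grid
#'
#' @param a an `abundance_maps` object.
#' @param grid a `map_grid` or `wet_map` defining the target grid.
#' @return an `abundance_maps` object on the target grid.
#' @export
resample_abundance <- function(a, grid) {
  maps <- lapply(a$maps, function(v) {
    vv <- v
    vv[is.na(vv)] <- 0
    wm <- wet_map(vv, spacing = a$spacing, origin = a$origin, mask = a$mask,
                  axis_names = a$axis_names, provenance = "abundance")
    resample_to_grid(wm, rigid_transform2d(), grid)
  })
  out <- list(maps = lapply(maps, `[[`, "values"),
              mask = maps[[1]]$mask,
              spacing = maps[[1]]$spacing, origin = maps[[1]]$origin,
              axis_names = a$axis_names)
  class(out) <- "abundance_maps"
  out
}

#' Correlate WET differences with material abundance
#'
#' Pearson correlation coefficient (in percent) between the relative WET
#' difference map and each material's abundance map over the jointly valid
#' pixels. A high positive coefficient indicates the WET error is driven by
#' overestimation of that material's stopping power (and vice versa).
#'
#' @param d a `diff_map`.
#' @param a an `abundance_maps` object on the same pixel grid.
#' @return data.frame with columns `material` and `correlation_pct`
#'   (`NA` when either map has zero variance).
#' @export
abundance_correlation <- function(d, a) {
  if (!all(abs(d$spacing - a$spacing) < 1e-6) ||
      !identical(dim(d$values), dim(a$maps[[1]]))) {
    stop("diff map and abundance maps must share a pixel grid")
  }
  mask <- d$mask & a$mask
  dv <- d$values[mask]
  cc <- vapply(a$maps, function(m) {
    av <- m[mask]
    if (sd(av) == 0 || sd(dv) == 0) return(NA_real_)
    100 * cor(dv, av)
  }, numeric(1))
  data.frame(material = names(a$maps), correlation_pct = unname(cc),
             stringsAsFactors = FALSE)
}
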