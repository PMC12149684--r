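# Procedural phantoms: a head-like nested-ellipsoid geometry whose imaged
# region reproduces the WET statistics of a base-of-skull radiograph, and
# homogeneous slabs for calibration work.

ellipsoid_field <- function(grid, center, semi) {
  u2 <- ((axis_coords(grid, 1) - center[1]) / semi[1])^2
  v2 <- ((axis_coords(grid, 2) - center[2]) / semi[2])^2
  w2 <- ((axis_coords(grid, 3) - center[3]) / semi[3])^2
  outer(outer(u2, v2, "+"), w2, "+")
}

ellipsoid_mask <- function(grid, center, semi) {
  ellipsoid_field(grid, center, semi) < 1
}

#' Default imaged region of the head phantom
#'
#' A 48 x 36 mm rectangle centred on the head in the projection plane
#' (coronal x axial), the size of the region imaged in base-of-skull
#' radiography with a 12 mm ROI tiling.
#'
#' @param grid the 3D `grid_spec` the phantom lives on.
#' @return numeric `c(min1, min2, width, height)` in mm (projection-plane
#'   axes: coronal, axial).
#' @export
default_imaged_region <- function(grid = default_reference_grid()) {
  ext <- grid_extent(grid)
  cy <- grid$origin[2] + ext[2] / 2
  cz <- grid$origin[3] + ext[3] / 2
  c(cy - 24, cz - 18, 48, 36)
}

# Head geometry for a given sagittal semi-axis; jit holds the seeded
# perturbations of the internal structures.
head_labels <- function(grid, table, ax, jit) {
  ext <- grid_extent(grid)
  hc <- grid$origin + ext / 2
  sp <- grid$spacing
  ay <- min(52, ext[2] / 2 - 3 * sp[2])
  az <- min(44, ext[3] / 2 - 3 * sp[3])
  ax <- min(ax, ext[1] / 2 - 3 * sp[1])
  semi <- c(ax, ay, az)
  shell <- 3

  id_of <- function(name) {
    k <- match(name, table$name)
    if (is.na(k)) material_id(table, "air") else table$id[k]
  }
  air <- material_id(table, "air")

  lab <- array(air, dim = grid$shape)
  outer_m <- ellipsoid_mask(grid, hc, semi)
  inner_m <- ellipsoid_mask(grid, hc, semi - shell)
  lab[outer_m] <- id_of("cortical_bone")
  lab[inner_m] <- id_of("soft_tissue")

  put <- function(lab, center, semi_s, name, where = inner_m) {
    m <- ellipsoid_mask(grid, center, semi_s) & where
    lab[m] <- id_of(name)
    lab
  }
  # trabecular bone patches
  lab <- put(lab, hc + c(0, 10, 8) + c(0, jit$t1), c(0.26 * ax, 12, 8) * jit$s1,
             "trabecular_bone")
  lab <- put(lab, hc + c(0, -16, 8) + c(0, jit$t2), c(0.18 * ax, 8, 6) * jit$s2,
             "trabecular_bone")
  # spinal cord: cylinder along the axial axis, outside the imaged region
  yc <- axis_coords(grid, 2) - (hc[2] + 32)
  xc <- axis_coords(grid, 1) - hc[1]
  r2 <- outer(xc^2, yc^2, "+") / 25
  zc <- axis_coords(grid, 3)
  inz <- abs(zc - hc[3]) <= 25
  cord <- outer(r2 < 1, inz, "&") & inner_m
  lab[cord] <- id_of("spinal_cord")
  # sinus cavity (low-RSP tissue) and two air cavities
  lab <- put(lab, hc + c(0, 12, -8) + c(0, jit$ts), c(0.22 * ax, 10, 7) * jit$ss,
             "sinus_cavity")
  lab <- put(lab, hc + c(0, -8, 4) + c(0, jit$ta), c(0.30 * ax, 14, 9) * jit$sa,
             "air")
  lab <- put(lab, hc + c(0, -12, -12) + c(0, jit$tb), c(0.13 * ax, 6, 5) * jit$sb,
             "air")
  # enforce an air boundary shell
  d <- dim(lab)
  lab[c(1, d[1]), , ] <- air
  lab[, c(1, d[2]), ] <- air
  lab[, , c(1, d[3])] <- air
  lab
}

#' Build the procedural head phantom
#'
#' A nested-ellipsoid head: cortical-bone shell, soft-tissue interior,
#' trabecular-bone patches, a spinal-cord cylinder, a sinus cavity and two
#' air cavities. The sagittal semi-axis is self-calibrated so that the mean
#' WET over the imaged region hits `target_mean_wet` (135 mm by default,
#' with every pixel inside roughly 90-180 mm, the regime of base-of-skull
#' imaging). The seed perturbs the internal structures slightly;
#' reconstruction of the same seed is bit-identical.
#'
#' @param grid 3D `grid_spec`; its sagittal extent must be at least 150 mm.
#' @param seed integer seed for the structural jitter.
#' @param table a `material_table`; materials missing from it degrade to air.
#' @param region imaged region rectangle (see [default_imaged_region()]).
#' @param target_mean_wet calibration target for the region mean WET in mm.
#' @param calibrate logical; disable to keep the nominal geometry.
#' @return a `label_volume`; the calibrated sagittal semi-axis and achieved
#'   region mean WET are attached as attributes `ax` and `mean_wet`.
#' @export
build_head_phantom <- function(grid = default_reference_grid(), seed = 7L,
                               table = build_material_table(),
                               region = default_imaged_region(grid),
                               target_mean_wet = 135, calibrate = TRUE) {
  ext <- grid_extent(grid)
  if (ext[1] < 150) {
    stop("grid too small: sagittal extent must be >= 150 mm to fit the head")
  }
  if (ext[2] < region[3] + 10 || ext[3] < region[4] + 10) {
    stop("grid too small to fit the imaged region")
  }
  jit <- with_seed(seed, list(
    t1 = runif(2, -1.5, 1.5), t2 = runif(2, -1.5, 1.5),
    ts = runif(2, -1.5, 1.5), ta = runif(2, -1.5, 1.5),
    tb = runif(2, -1.5, 1.5),
    s1 = runif(1, 0.96, 1.04), s2 = runif(1, 0.96, 1.04),
    ss = runif(1, 0.96, 1.04), sa = runif(1, 0.96, 1.04),
    sb = runif(1, 0.96, 1.04)
  ))

  mean_region_wet <- function(ax) {
    lab <- head_labels(grid, table, ax, jit)
    lv <- label_volume(lab, grid, table)
    wm <- project_wet(assign_rsp(lv), "sagittal")
    cr <- crop_region(wm, region)
    list(mean = mean(cr$values[cr$mask]), lv = lv)
  }

  can_calibrate <- calibrate &&
    all(c("air", "soft_tissue", "cortical_bone") %in% table$name)
  ax <- 76
  if (!can_calibrate) {
    res <- mean_region_wet(ax)
  } else {
    # secant iteration on the sagittal semi-axis; d(mean WET)/d(ax) ~ 1.9/mm
    res <- mean_region_wet(ax)
    f0 <- res$mean - target_mean_wet
    if (abs(f0) > 0.25) {
      ax1 <- ax + -f0 / 1.9
      res1 <- mean_region_wet(ax1)
      f1 <- res1$mean - target_mean_wet
      it <- 0
      while (abs(f1) > 0.25 && it < 6 && abs(f1 - f0) > 1e-9) {
        ax2 <- ax1 - f1 * (ax1 - ax) / (f1 - f0)
        ax <- ax1; f0 <- f1
        ax1 <- ax2
        res1 <- mean_region_wet(ax1)
        f1 <- res1$mean - target_mean_wet
        it <- it + 1
      }
      ax <- ax1
      res <- res1
    }
  }
  lv <- res$lv
  attr(lv, "ax") <- ax
  attr(lv, "mean_wet") <- res$mean
  attr(lv, "region") <- region
  lv
}

#' Build a homogeneous slab phantom
#'
#' A slab of one material, oriented perpendicular to the sagittal axis, whose
#' sagittal WET equals `wet_mm` to within half a voxel's WET.
#'
#' @param wet_mm target water-equivalent thickness in mm (> 0).
#' @param rsp relative stopping power of the slab material.
#' @param grid 3D `grid_spec`; default 200 x 30 x 20 mm at 0.5 mm.
#' @param name material name for the slab.
#' @return a `label_volume`.
#' @export
build_slab_phantom <- function(wet_mm, rsp = 1.0,
                               grid = grid_spec(c(400L, 60L, 40L),
                                                c(0.5, 0.5, 0.5)),
                               name = "water") {
  if (wet_mm <= 0) stop("wet_mm must be > 0")
  if (rsp <= 0.0011) stop("slab rsp must exceed the rsp of air")
  dx <- grid$spacing[1]
  nvox <- round(wet_mm / (rsp * dx))
  if (nvox > grid$shape[1] - 2L) {
    stop("slab thickness exceeds the grid extent along the sagittal axis")
  }
  table <- build_material_table(data.frame(
    id = c(0L, 1L), name = c("air", name), rsp = c(0.0011, rsp),
    bias_sect = c(1, 1), bias_dect = c(1, 1), stringsAsFactors = FALSE))
  lab <- array(0L, dim = grid$shape)
  i0 <- max(2L, (grid$shape[1] - nvox) %/% 2L)
  lab[i0:(i0 + nvox - 1L), 2:(grid$shape[2] - 1L), 2:(grid$shape[3] - 1L)] <- 1L
  label_volume(lab, grid, table)
}
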