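#' Regular 3D voxel grid specification
#'
#' World coordinates follow the voxel-center convention: the centre of voxel
#' `i` (1-based) along an axis lies at `origin + (i - 0.5) * spacing`. One
#' axis must be named `"sagittal"`; it is the projection axis used to turn
#' RSP volumes into WET maps.
#'
#' @param shape integer vector of length 3, voxels per axis.
#' @param spacing numeric vector of length 3, mm per voxel along each axis.
#' @param origin numeric vector of length 3, world position (mm) of the
#'   low corner of the grid.
#' @param axis_names character vector of length 3 naming the axes.
#' @return an object of class `grid_spec`.
#' @export
grid_spec <- function(shape, spacing, origin = c(0, 0, 0),
                      axis_names = c("sagittal", "coronal", "axial")) {
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  stopifnot(length(shape) == 3L, length(spacing) == 3L, length(origin) == 3L,
            length(axis_names) == 3L)
  if (any(shape < 1L)) stop("grid shape must be >= 1 on every axis")
  if (any(spacing <= 0)) stop("grid spacing must be > 0 on every axis")
  structure(list(shape = shape, spacing = spacing, origin = origin,
                 axis_names = axis_names),
            class = "grid_spec")
}

#' Default high-resolution reference grid (0.5 mm isotropic)
#'
#' Covers 170 x 120 x 100 mm, enough for the default head phantom with an
#' air margin on every face.
#' @return a `grid_spec`.
#' @export
default_reference_grid <- function() {
  grid_spec(shape = c(340L, 240L, 200L), spacing = c(0.5, 0.5, 0.5))
}

#' Default clinical CT grid (0.9766 x 0.9766 x 1.5 mm)
#'
#' The voxel size of a typical clinical head protocol; modality volumes are
#' resampled onto this grid.
#' @param reference a `grid_spec` whose world extent the clinical grid
#'   should cover (defaults to [default_reference_grid()]).
#' @return a `grid_spec`.
#' @export
default_clinical_grid <- function(reference = default_reference_grid()) {
  sp <- c(0.9766, 0.9766, 1.5)
  ext <- grid_extent(reference)
  grid_spec(shape = pmax(1L, floor(ext / sp)), spacing = sp,
            origin = reference$origin, axis_names = reference$axis_names)
}

#' @rdname grid_spec
#' @param grid a `grid_spec`.
#' @return `grid_extent`: world extent in mm per axis.
#' @export
grid_extent <- function(grid) grid$shape * grid$spacing

# Voxel-centre world coordinates along one axis.
axis_coords <- function(grid, axis) {
  i <- seq_len(grid$shape[axis])
  grid$origin[axis] + (i - 0.5) * grid$spacing[axis]
}

# Index of the named axis, with a clear error for unknown names.
axis_index <- function(grid, axis) {
  if (is.numeric(axis)) {
    axis <- as.integer(axis)
    if (axis < 1L || axis > 3L) stop("axis index out of range")
    return(axis)
  }
  k <- match(axis, grid$axis_names)
  if (is.na(k)) {
    stop(sprintf("unknown axis '%s'; grid axes are: %s", axis,
                 paste(grid$axis_names, collapse = ", ")))
  }
  k
}

same_grid <- function(a, b, tol = 1e-9) {
  identical(a$shape, b$shape) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

#' @export
print.grid_spec <- function(x, ...) {
  cat("grid_spec:", paste(x$shape, collapse = " x "), "voxels, spacing",
      paste(format(x$spacing), collapse = " x "), "mm\n")
  cat("  axes:", paste(x$axis_names, collapse = ", "),
      "| extent:", paste(format(grid_extent(x)), collapse = " x "), "mm\n")
  invisible(x)
}
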