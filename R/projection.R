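#' 2D water-equivalent thickness map
#'
#' WET in mm on a regular pixel grid in the projection plane, with a
#' per-pixel validity mask. Pixel centres follow the same half-pixel
#' convention as [grid_spec()].
#'
#' @param values numeric matrix of WET (mm).
#' @param spacing pixel spacing (mm) for the two in-plane axes.
#' @param origin world position (mm) of the low corner.
#' @param mask logical matrix of valid pixels (default: all valid).
#' @param axis_names names of the two in-plane axes.
#' @param provenance free-text provenance tag.
#' @return a `wet_map`.
#' @export
wet_map <- function(values, spacing = c(0.98, 1.5), origin = c(0, 0),
                    mask = NULL, axis_names = c("coronal", "axial"),
                    provenance = "unknown") {
  values <- as.matrix(values)
  if (is.null(mask)) mask <- array(TRUE, dim(values))
  mask <- as.matrix(mask)
  stopifnot(identical(dim(values), dim(mask)))
  if (any(spacing <= 0)) stop("pixel spacing must be > 0")
  if (any(values[mask] < 0, na.rm = TRUE)) stop("WET must be >= 0 where valid")
  structure(list(values = values, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), mask = mask,
                 axis_names = axis_names, provenance = provenance),
            class = "wet_map")
}

map_coords <- function(map, axis) {
  i <- seq_len(dim(map$values)[axis])
  map$origin[axis] + (i - 0.5) * map$spacing[axis]
}

same_map_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$values), dim(b$values)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

#' Strip external air from an RSP volume
#'
#' Voxels with RSP below `threshold` that are 6-connected to the volume
#' boundary are set to zero; enclosed cavities are untouched. The default
#' threshold of 0.05 separates air (RSP about 0.001) from the lowest-RSP
#' tissue surrogate (sinus, about 0.2).
#'
#' @param rsp an `rsp_volume`.
#' @param threshold RSP threshold (> 0).
#' @return the stripped `rsp_volume`; the external-air mask is attached as
#'   attribute `external_mask`.
#' @export
strip_external_air <- function(rsp, threshold = 0.05) {
  stopifnot(inherits(rsp, "rsp_volume"), threshold > 0)
  ext <- external_air_mask(rsp, threshold)
  vals <- rsp$values
  vals[ext] <- 0
  out <- rsp_volume(vals, rsp$grid, rsp$provenance)
  attr(out, "external_mask") <- ext
  out
}

#' @rdname strip_external_air
#' @return `external_air_mask`: logical array, TRUE for boundary-connected
#'   sub-threshold voxels.
#' @export
external_air_mask <- function(rsp, threshold = 0.05) {
  fillable <- rsp$values < threshold
  ext <- flood_from_boundary(as.logical(fillable), rsp$grid$shape)
  dim(ext) <- rsp$grid$shape
  ext
}

#' Project an RSP volume to a WET map
#'
#' Discrete line integral of RSP along the named axis: the voxel values are
#' summed and multiplied by the voxel size along that axis, giving WET in mm
#' water. A pixel is valid if any nonzero voxel contributed to it.
#'
#' @param rsp an `rsp_volume`.
#' @param axis axis name (default the sagittal axis) or index.
#' @return a `wet_map` on the projected pixel grid.
#' @export
project_wet <- function(rsp, axis = "sagittal") {
  k <- axis_index(rsp$grid, axis)
  vals <- rsp$values
  if (k != 1L) vals <- aperm(vals, c(k, setdiff(1:3, k)))
  keep <- setdiff(1:3, k)
  d <- dim(vals)
  m <- matrix(vals, nrow = d[1])
  wet <- colSums(m) * rsp$grid$spacing[k]
  contrib <- colSums(m != 0) > 0
  dim(wet) <- d[2:3]
  dim(contrib) <- d[2:3]
  wet_map(wet, spacing = rsp$grid$spacing[keep], origin = rsp$grid$origin[keep],
          mask = contrib, axis_names = rsp$grid$axis_names[keep],
          provenance = rsp$provenance)
}

#' Crop a WET map to a world-coordinate rectangle
#'
#' Pixel counts use the ceiling convention (a 48 mm width at 0.98 mm spacing
#' gives 49 pixels); world coordinates and spacing are preserved.
#'
#' @param map a `wet_map`.
#' @param rect_mm numeric `c(min1, min2, width, height)` in mm.
#' @return the cropped `wet_map`.
#' @export
crop_region <- function(map, rect_mm) {
  stopifnot(length(rect_mm) == 4, rect_mm[3] > 0, rect_mm[4] > 0)
  d <- dim(map$values)
  idx <- vector("list", 2L)
  for (a in 1:2) {
    i0 <- floor((rect_mm[a] - map$origin[a]) / map$spacing[a] + 1e-9) + 1L
    n <- ceiling(rect_mm[a + 2] / map$spacing[a] - 1e-9)
    if (i0 < 1L || i0 + n - 1L > d[a]) {
      stop("crop rectangle extends outside the map bounds")
    }
    idx[[a]] <- seq.int(i0, i0 + n - 1L)
  }
  wet_map(map$values[idx[[1]], idx[[2]], drop = FALSE],
          spacing = map$spacing,
          origin = map$origin + (c(idx[[1]][1], idx[[2]][1]) - 1L) * map$spacing,
          mask = map$mask[idx[[1]], idx[[2]], drop = FALSE],
          axis_names = map$axis_names, provenance = map$provenance)
}

#' Write / read WET maps
#'
#' CSV stores the raw value matrix (invalid pixels as NA) with spacing and
#' origin in a header comment; NIfTI stores a single-slice image.
#'
#' @param map a `wet_map`.
#' @param path output file.
#' @export
write_wet_csv <- function(map, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# wet_map spacing=%g,%g origin=%g,%g provenance=%s",
                     map$spacing[1], map$spacing[2],
                     map$origin[1], map$origin[2], map$provenance), con)
  vals <- map$values
  vals[!map$mask] <- NA
  utils::write.table(vals, con, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_wet_csv
#' @export
read_wet_csv <- function(path) {
  hdr <- readLines(path, n = 1L)
  m <- regmatches(hdr, regexec(
    "spacing=([-0-9.e]+),([-0-9.e]+) origin=([-0-9.e]+),([-0-9.e]+) provenance=(\\S+)",
    hdr))[[1]]
  vals <- as.matrix(read.csv(path, header = FALSE, skip = 1L,
                             comment.char = "#"))
  dimnames(vals) <- NULL
  mask <- !is.na(vals)
  vals[!mask] <- 0
  wet_map(vals, spacing = as.numeric(m[2:3]), origin = as.numeric(m[4:5]),
          mask = mask, provenance = m[6])
}

#' @rdname write_wet_csv
#' @export
write_wet_nifti <- function(map, path) {
  vals <- map$values
  vals[!map$mask] <- -1
  img <- RNifti::asNifti(array(vals, dim = c(dim(vals), 1L)))
  img <- RNifti::`pixdim<-`(img, c(map$spacing, 1))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @export
print.wet_map <- function(x, ...) {
  v <- x$values[x$mask]
  cat("wet_map (", x$provenance, "): ", paste(dim(x$values), collapse = " x "),
      " px at ", paste(format(x$spacing), collapse = " x "), " mm\n", sep = "")
  if (length(v)) {
    cat(sprintf("  WET range [%.1f, %.1f] mm, mean %.1f mm over %d valid px\n",
                min(v), max(v), mean(v), length(v)))
  }
  invisible(x)
}
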