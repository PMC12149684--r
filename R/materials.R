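#' Tissue-surrogate material table
#'
#' Each material carries a dimensionless relative stopping power (RSP) and
#' two multiplicative bias factors used when emulating single-energy
#' (SECT-HLUT) and dual-energy (DECT-DirectSPR) CT stopping-power volumes.
#' The default table holds the six materials the head phantom is built
#' from. The RSP values are plausible surrogate values chosen for this
#' simulator, not measured ones; the bias factors encode the trends
#' observed clinically (air and sinus tissue overestimated, cortical bone
#' underestimated, with smaller magnitudes for DECT than for SECT).
#'
#' @param config a data.frame with columns `id`, `name`, `rsp` and
#'   optionally `bias_sect`, `bias_dect` (default 1 where absent), or NULL
#'   for the default six-material table.
#' @return a `material_table` (a data.frame).
#' @export
#' @examples
#' build_material_table()
build_material_table <- function(config = NULL) {
  if (is.null(config)) config <- default_materials()
  config <- as.data.frame(config, stringsAsFactors = FALSE)
  need <- c("id", "name", "rsp")
  if (!all(need %in% names(config))) {
    stop("material config needs columns: ", paste(need, collapse = ", "))
  }
  if (nrow(config) < 2L) stop("material table needs at least 2 materials")
  if (anyDuplicated(config$id)) stop("duplicate material labels (id)")
  if (anyDuplicated(config$name)) stop("duplicate material names")
  if (any(!is.finite(config$rsp)) || any(config$rsp < 0)) {
    stop("material rsp must be finite and >= 0")
  }
  if (is.null(config$bias_sect)) config$bias_sect <- 1
  if (is.null(config$bias_dect)) config$bias_dect <- 1
  if ("air" %in% config$name &&
      config$rsp[config$name == "air"] > min(config$rsp)) {
    stop("air must have the minimum rsp of the table")
  }
  if ("cortical_bone" %in% config$name &&
      config$rsp[config$name == "cortical_bone"] < max(config$rsp)) {
    stop("cortical_bone must have the maximum rsp of the table")
  }
  config$id <- as.integer(config$id)
  class(config) <- c("material_table", "data.frame")
  config
}

#' @rdname build_material_table
#' @export
default_materials <- function() {
  data.frame(
    id = 0:5,
    name = c("air", "sinus_cavity", "soft_tissue", "spinal_cord",
             "trabecular_bone", "cortical_bone"),
    rsp = c(0.0011, 0.20, 1.04, 1.04, 1.11, 1.60),
    bias_sect = c(1.30, 1.08, 1.005, 1.005, 0.995, 0.975),
    bias_dect = c(1.15, 1.04, 1.0025, 1.0025, 0.9975, 0.985),
    stringsAsFactors = FALSE
  )
}

material_id <- function(table, name) {
  k <- match(name, table$name)
  if (is.na(k)) stop(sprintf("material '%s' not in table", name))
  table$id[k]
}

#' Read / write a material table as CSV
#'
#' @param path file path.
#' @param table a `material_table`.
#' @return `read_material_table` returns a `material_table`.
#' @export
read_material_table <- function(path) {
  build_material_table(read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_material_table
#' @export
write_material_table <- function(table, path) {
  write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}
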