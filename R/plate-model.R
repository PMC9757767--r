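VALID_ROLES <- c("negative-control", "positive-control", "test")

#' Treatment annotation for one well
#'
#' @param compound compound (or vehicle) label.
#' @param concentration concentration in umol/L; 0 for controls.
#' @param role one of `"negative-control"`, `"positive-control"`, `"test"`.
#' @return a `treatment_spec` list.
#' @export
treatment_spec <- function(compound, concentration, role) {
  if (!role %in% VALID_ROLES) {
    stop_fibrescreen("unknown treatment role '%s'", role, class = "manifest_error")
  }
  concentration <- as.numeric(concentration)
  if (role == "negative-control" && concentration != 0) {
    stop_fibrescreen(
      "negative-control wells must have concentration 0 (got %g)",
      concentration, class = "manifest_error"
    )
  }
  structure(
    list(compound = compound, concentration = concentration, role = role),
    class = "treatment_spec"
  )
}

#' Validate a 384-well address
#'
#' Rows A-P, columns 1-24, e.g. "A1", "P24".
#'
#' @param well character vector of addresses.
#' @return logical vector.
#' @export
is_well_address <- function(well) {
  ok <- grepl("^[A-P]([1-9]|1[0-9]|2[0-4])$", well)
  ok & !is.na(well)
}

#' All 384-well addresses in row-major order
#' @return character vector "A1".."P24".
#' @export
well_addresses_384 <- function() {
  as.vector(t(outer(LETTERS[1:16], 1:24, paste0)))
}

#' Plate layout: well-to-treatment map for one replicate plate
#'
#' @param plate_id plate identifier.
#' @param wells data.frame with columns `well`, `compound`, `concentration`,
#'   `role` (one row per well).
#' @param replicate_index replicate (screen day) index, >= 1.
#' @return a `plate_layout` object.
#' @export
plate_layout <- function(plate_id, wells, replicate_index = 1L) {
  stopifnot(is.data.frame(wells))
  need <- c("well", "compound", "concentration", "role")
  miss <- setdiff(need, names(wells))
  if (length(miss)) {
    stop_fibrescreen("layout is missing columns: %s",
                     paste(miss, collapse = ", "), class = "manifest_error")
  }
  if (anyDuplicated(wells$well)) {
    stop_fibrescreen("duplicate well addresses in plate '%s'", plate_id,
                     class = "manifest_error")
  }
  bad <- wells$well[!is_well_address(wells$well)]
  if (length(bad)) {
    stop_fibrescreen("invalid 384-well address(es): %s",
                     paste(utils::head(bad, 5), collapse = ", "),
                     class = "manifest_error")
  }
  if (!all(wells$role %in% VALID_ROLES)) {
    stop_fibrescreen("unknown role string(s): %s",
                     paste(unique(setdiff(wells$role, VALID_ROLES)), collapse = ", "),
                     class = "manifest_error")
  }
  if (!any(wells$role == "negative-control")) {
    stop_fibrescreen("plate '%s' has no negative-control well", plate_id,
                     class = "manifest_error")
  }
  if (replicate_index < 1) {
    stop_fibrescreen("replicate_index must be >= 1", class = "manifest_error")
  }
  structure(
    list(plate_id = as.character(plate_id), wells = wells,
         replicate_index = as.integer(replicate_index)),
    class = "plate_layout"
  )
}

#' @export
print.plate_layout <- function(x, ...) {
  cat(sprintf("<plate_layout> %s (replicate %d): %d wells (%d negative-control, %d positive-control, %d test)\n",
              x$plate_id, x$replicate_index, nrow(x$wells),
              sum(x$wells$role == "negative-control"),
              sum(x$wells$role == "positive-control"),
              sum(x$wells$role == "test")))
  invisible(x)
}

#' One imaged field of view: paired matrix / nuclei z-stacks
#'
#' Stacks are 3-D arrays indexed `[row, col, z]` with intensities in arbitrary
#' fluorescence units on the 16-bit scale (0..65535).  The acquisition default
#' is a z-stack through 8 um depth at 1 um intervals (9 slices).
#'
#' @param well well address.
#' @param fov_index field-of-view index within the well (1..4).
#' @param matrix_stack,nuclei_stack 3-D numeric arrays of identical shape.
#' @param z_step z interval in um.
#' @param z_depth total z depth in um.
#' @return an `fov_stack` object.
#' @export
fov_stack <- function(well, fov_index, matrix_stack, nuclei_stack,
                      z_step = 1, z_depth = 8) {
  if (!is.array(matrix_stack) || length(dim(matrix_stack)) != 3L ||
      !is.array(nuclei_stack) || length(dim(nuclei_stack)) != 3L) {
    stop_fibrescreen("stacks must be 3-D arrays [row, col, z]",
                     class = "layout_error")
  }
  if (!identical(dim(matrix_stack), dim(nuclei_stack))) {
    stop_fibrescreen(
      "matrix and nuclei stacks differ in shape (%s vs %s)",
      paste(dim(matrix_stack), collapse = "x"),
      paste(dim(nuclei_stack), collapse = "x"),
      class = "layout_error"
    )
  }
  if (min(matrix_stack) < 0 || min(nuclei_stack) < 0) {
    stop_fibrescreen("stack intensities must be non-negative",
                     class = "layout_error")
  }
  if (!fov_index %in% 1:4) {
    stop_fibrescreen("fov_index must be in 1..4 (got %s)", fov_index,
                     class = "layout_error")
  }
  structure(
    list(well = well, fov_index = as.integer(fov_index),
         matrix_stack = matrix_stack, nuclei_stack = nuclei_stack,
         z_step = z_step, z_depth = z_depth),
    class = "fov_stack"
  )
}

#' @export
print.fov_stack <- function(x, ...) {
  d <- dim(x$matrix_stack)
  cat(sprintf("<fov_stack> well %s fov %d: 2 channels, %d slice(s) of %dx%d (z %g um / %g um depth)\n",
              x$well, x$fov_index, d[3], d[1], d[2], x$z_step, x$z_depth))
  invisible(x)
}

#' Maximum-intensity projection of a field-of-view stack
#'
#' Each output pixel is the maximum of that pixel across all z slices,
#' computed independently for the matrix and nuclei channels.
#'
#' @param stack an `fov_stack`, or a bare 3-D array `[row, col, z]`.
#' @return for an `fov_stack`, a `projected_fov` list with `matrix_mip`,
#'   `nuclei_mip` and provenance fields; for a bare array, the projected
#'   matrix.
#' @export
max_project <- function(stack) {
  if (is.array(stack) && length(dim(stack)) == 3L) {
    return(mip_array(stack))
  }
  if (!inherits(stack, "fov_stack")) {
    stop_fibrescreen("max_project expects an fov_stack or a 3-D array",
                     class = "contract_error")
  }
  structure(
    list(matrix_mip = mip_array(stack$matrix_stack),
         nuclei_mip = mip_array(stack$nuclei_stack),
         well = stack$well, fov_index = stack$fov_index),
    class = "projected_fov"
  )
}

mip_array <- function(a) {
  d <- dim(a)
  if (is.null(d) || length(d) != 3L || any(d == 0L)) {
    stop_fibrescreen("cannot project an empty stack", class = "contract_error")
  }
  out <- a[, , 1L]
  if (d[3] > 1L) {
    for (k in 2:d[3]) out <- pmax(out, a[, , k])
  }
  out
}
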