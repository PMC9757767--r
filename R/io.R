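#' Write a field-of-view stack to a multi-page TIFF
#'
#' One file per FOV; pages are ordered z-major with the channel varying
#' fastest (z1/matrix, z1/nuclei, z2/matrix, ...).  Intensities are stored as
#' 16-bit unsigned integers, so values are clipped to 0..65535 and rounded.
#'
#' @param stack an [fov_stack()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fov_stack <- function(stack, path) {
  stopifnot(inherits(stack, "fov_stack"))
  d <- dim(stack$matrix_stack)
  pages <- vector("list", 2L * d[3])
  for (k in seq_len(d[3])) {
    pages[[2L * k - 1L]] <- pmin(pmax(round(stack$matrix_stack[, , k]), 0), 65535) / 65535
    pages[[2L * k]]      <- pmin(pmax(round(stack$nuclei_stack[, , k]), 0), 65535) / 65535
  }
  ok <- try(tiff::writeTIFF(pages, path, bits.per.sample = 16L), silent = TRUE)
  if (inherits(ok, "try-error")) {
    stop_fibrescreen("cannot write TIFF '%s'", path, class = "io_error")
  }
  invisible(path)
}

#' Read a field-of-view stack from a multi-page TIFF
#'
#' The channel/z layout must be declared by the caller (via the manifest or a
#' config), never guessed from pixel content: pages are z-major with
#' `n_channels` channels interleaved per z plane (matrix channel first).
#'
#' @param path TIFF file path.
#' @param well,fov_index identity metadata (from the manifest).
#' @param n_channels number of interleaved channels the file must contain.
#' @param z_step,z_depth acquisition metadata in um.
#' @return an [fov_stack()].
#' @export
read_fov_stack <- function(path, well = "A1", fov_index = 1L,
                           n_channels = 2L, z_step = 1, z_depth = 8) {
  if (!file.exists(path)) {
    stop_fibrescreen("cannot read TIFF '%s': no such file", path,
                     class = "io_error")
  }
  pages <- try(tiff::readTIFF(path, all = TRUE, as.is = TRUE), silent = TRUE)
  if (inherits(pages, "try-error")) {
    stop_fibrescreen("cannot read TIFF '%s'", path, class = "io_error")
  }
  if (!is.list(pages)) pages <- list(pages)
  n <- length(pages)
  if (n %% n_channels != 0L) {
    stop_fibrescreen(
      "TIFF '%s' has %d pages, not a multiple of the %d declared channels",
      path, n, n_channels, class = "layout_error"
    )
  }
  nz <- n %/% n_channels
  if (nz < 1L) {
    stop_fibrescreen("TIFF '%s' is empty", path, class = "layout_error")
  }
  shp <- dim(pages[[1]])
  if (!all(vapply(pages, function(p) identical(dim(p), shp), logical(1)))) {
    stop_fibrescreen("TIFF '%s' pages differ in shape", path,
                     class = "layout_error")
  }
  grab <- function(ch) {
    a <- array(0, c(shp[1], shp[2], nz))
    for (k in seq_len(nz)) a[, , k] <- pages[[(k - 1L) * n_channels + ch]]
    a
  }
  mat <- grab(1L)
  nuc <- if (n_channels >= 2L) grab(2L) else mat * 0
  fov_stack(well, fov_index, mat, nuc, z_step = z_step, z_depth = z_depth)
}

#' Load a plate manifest
#'
#' The manifest is a delimited table with columns `plate`, `well`, `fov`,
#' `path`, `compound`, `concentration`, `role`; one row per FOV image file.
#' Wells with fewer than 4 FOV rows are accepted (the QC cascade handles
#' them); duplicated (plate, well, fov) rows and unknown roles are errors, as
#' is a plate without a negative-control well.
#'
#' @param manifest a file path or a data.frame.
#' @return a list with `layouts` (one [plate_layout()] per plate) and `fovs`
#'   (the validated manifest data.frame).
#' @export
load_plate <- function(manifest) {
  m <- if (is.character(manifest)) {
    utils::read.csv(manifest, stringsAsFactors = FALSE)
  } else {
    as.data.frame(manifest, stringsAsFactors = FALSE)
  }
  need <- c("plate", "well", "fov", "path", "compound", "concentration", "role")
  miss <- setdiff(need, names(m))
  if (length(miss)) {
    stop_fibrescreen("manifest is missing columns: %s",
                     paste(miss, collapse = ", "), class = "manifest_error")
  }
  key <- paste(m$plate, m$well, m$fov)
  if (anyDuplicated(key)) {
    stop_fibrescreen("duplicate (plate, well, fov) rows in manifest: %s",
                     key[duplicated(key)][1], class = "manifest_error")
  }
  if (!all(m$fov %in% 1:4)) {
    stop_fibrescreen("fov indices must be in 1..4", class = "manifest_error")
  }
  layouts <- lapply(split(m, m$plate), function(p) {
    wells <- unique(p[, c("well", "compound", "concentration", "role")])
    if (anyDuplicated(wells$well)) {
      stop_fibrescreen(
        "well %s of plate %s has conflicting treatment annotations",
        wells$well[duplicated(wells$well)][1], p$plate[1],
        class = "manifest_error"
      )
    }
    rep_idx <- if ("replicate" %in% names(p)) p$replicate[1] else 1L
    plate_layout(p$plate[1], wells, replicate_index = rep_idx)
  })
  list(layouts = layouts, fovs = m)
}

#' Write a results table as CSV
#'
#' Deterministic column order (as given); re-reading with [read_results()]
#' reproduces integer columns bit-exactly and reals to full printed precision
#' (15 significant digits).
#'
#' @param table non-empty data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(table, path) {
  if (!is.data.frame(table) || nrow(table) == 0L) {
    stop_fibrescreen("results table is empty", class = "contract_error")
  }
  out <- table
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.15g", out[[j]])
  }
  ok <- try(utils::write.csv(out, path, row.names = FALSE, quote = TRUE),
            silent = TRUE)
  if (inherits(ok, "try-error")) {
    stop_fibrescreen("cannot write results to '%s'", path, class = "io_error")
  }
  invisible(path)
}

#' Read back a results table written by [write_results()]
#' @param path CSV path.
#' @return data.frame.
#' @export
read_results <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read a YAML or JSON configuration file
#'
#' All pipeline thresholds (background level, QC fractions, structure-tensor
#' sigmas, simulator parameters) are surfaced as config keys; values present
#' in the file override the built-in defaults.
#'
#' @param path YAML (or JSON, a YAML subset) file path.
#' @return a named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    stop_fibrescreen("config file '%s' not found", path, class = "io_error")
  }
  yaml::read_yaml(path)
}
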