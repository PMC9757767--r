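# Three-tier exclusion cascade: field of view (insufficient matrix or imaging
# error), well (too few valid FOV, toxicity), treatment (too few valid
# replicate wells).  Boundary conventions are read literally from the screen's
# printed rules: pixels "at or below" background use <=, FOV flagging uses
# strict > 10 percent, toxicity uses strict < 40 percent of control nuclei.

#' Quality-control configuration
#'
#' @param background_level intensity threshold in a.u. below which a pixel is
#'   considered background (default 100, tied to the 16-bit intensity scale;
#'   adapt for other imaging setups).
#' @param max_background_fraction maximum tolerated fraction of background
#'   pixels per FOV (default 0.10; flagging is strict `>`).
#' @param min_valid_fov minimum unflagged FOV per well (default 3 of 4).
#' @param min_nuclei_percent toxicity cutoff in percent of control nuclei
#'   (default 40; exclusion is strict `<`).
#' @param min_valid_wells minimum valid replicate wells per treatment
#'   (default 2 of 3).
#' @return a `qc_config` list.
#' @export
qc_config <- function(background_level = 100, max_background_fraction = 0.10,
                      min_valid_fov = 3L, min_nuclei_percent = 40,
                      min_valid_wells = 2L) {
  if (background_level <= 0 || min_nuclei_percent <= 0) {
    stop_fibrescreen("thresholds must be strictly positive",
                     class = "parameter_error")
  }
  if (max_background_fraction <= 0 || max_background_fraction >= 1) {
    stop_fibrescreen("max_background_fraction must be in (0, 1)",
                     class = "parameter_error")
  }
  structure(
    list(background_level = background_level,
         max_background_fraction = max_background_fraction,
         min_valid_fov = as.integer(min_valid_fov),
         min_nuclei_percent = min_nuclei_percent,
         min_valid_wells = as.integer(min_valid_wells)),
    class = "qc_config"
  )
}

#' Fraction of background pixels in a matrix-channel projection
#'
#' Counts pixels at or below (`<=`) the background level.
#'
#' @param mip 2-D matrix-channel maximum-intensity projection.
#' @param background_level background threshold in a.u. (default 100).
#' @return fraction in [0, 1].
#' @export
background_fraction <- function(mip, background_level = 100) {
  if (length(mip) == 0L) {
    stop_fibrescreen("empty projection", class = "contract_error")
  }
  mean(mip <= background_level)
}

#' Flag a field of view for insufficient matrix
#'
#' A FOV is flagged (and excluded from alignment analysis) iff its background
#' fraction strictly exceeds `max_background_fraction`; exactly 10 percent
#' passes.
#'
#' @param fraction background fraction in [0, 1].
#' @param config a [qc_config()].
#' @return `NULL` if the FOV passes, else a `qc_flag` list
#'   (level `"fov"`, reason `"insufficient_matrix"`, measured value).
#' @export
flag_fov <- function(fraction, config = qc_config()) {
  stopifnot(fraction >= 0, fraction <= 1)
  if (fraction > config$max_background_fraction) {
    qc_flag("fov", "insufficient_matrix", fraction)
  } else {
    NULL
  }
}

qc_flag <- function(level, reason, value) {
  structure(list(level = level, reason = reason, value = value),
            class = "qc_flag")
}

#' @export
print.qc_flag <- function(x, ...) {
  cat(sprintf("<qc_flag> level=%s reason=%s value=%.4g\n",
              x$level, x$reason, x$value))
  invisible(x)
}

#' Flag a well for too few valid FOV and/or toxicity
#'
#' A well is excluded when 2 or more of its 4 FOV are flagged
#' (`too_few_fov`), or when its nuclei count falls strictly below 40 percent
#' of the control baseline (`toxicity`).  Both flags may co-occur; the well
#' counts once as excluded with both reasons retained.
#'
#' @param fov_flagged logical vector of per-FOV flag states (1-4 entries).
#' @param nuclei_percent nuclei percent-of-control for the well (NA to skip
#'   the toxicity rule, e.g. when no nuclei channel was acquired).
#' @param config a [qc_config()].
#' @return list of `qc_flag`s (empty if the well is retained).
#' @export
flag_well <- function(fov_flagged, nuclei_percent = NA_real_,
                      config = qc_config()) {
  if (length(fov_flagged) == 0L) {
    stop_fibrescreen("well has no FOV records", class = "contract_error")
  }
  flags <- list()
  n_valid <- sum(!fov_flagged)
  if (n_valid < config$min_valid_fov) {
    flags <- c(flags, list(qc_flag("well", "too_few_fov", n_valid)))
  }
  if (!is.na(nuclei_percent) && nuclei_percent < config$min_nuclei_percent) {
    flags <- c(flags, list(qc_flag("well", "toxicity", nuclei_percent)))
  }
  flags
}

#' Flag a treatment condition with too few valid replicate wells
#'
#' A (compound, concentration) condition is dropped from the hit list when 2
#' or more of its replicate wells were excluded -- equivalently, composite
#' scoring requires at least `min_valid_wells` valid replicates.
#'
#' @param well_valid logical vector of per-replicate well validity.
#' @param config a [qc_config()].
#' @return `NULL` if the treatment is retained, else a `qc_flag`
#'   (level `"treatment"`, reason `"too_few_wells"`).
#' @export
flag_treatment <- function(well_valid, config = qc_config()) {
  n_valid <- sum(well_valid)
  if (n_valid < config$min_valid_wells) {
    qc_flag("treatment", "too_few_wells", n_valid)
  } else {
    NULL
  }
}

#' Summarise the QC cascade
#'
#' Buckets every excluded well into exactly one of: insufficient matrix only,
#' toxicity only, or both, so the accounting identity
#' `excluded = matrix_only + toxicity_only + both` holds by construction.
#'
#' @param well_table data.frame with logical columns `matrix_fail` (too few
#'   valid FOV) and `toxicity_fail` per well.
#' @return a `qc_report` list of counts plus the per-reason well lists.
#' @export
qc_report <- function(well_table) {
  stopifnot(all(c("matrix_fail", "toxicity_fail") %in% names(well_table)))
  m <- well_table$matrix_fail
  t <- well_table$toxicity_fail & !is.na(well_table$toxicity_fail)
  both <- m & t
  matrix_only <- m & !t
  toxicity_only <- t & !m
  id <- if (all(c("plate", "well") %in% names(well_table))) {
    paste(well_table$plate, well_table$well)
  } else {
    as.character(seq_len(nrow(well_table)))
  }
  structure(
    list(total_wells = nrow(well_table),
         excluded = sum(both | matrix_only | toxicity_only),
         matrix_only = sum(matrix_only),
         toxicity_only = sum(toxicity_only),
         both = sum(both),
         matrix_only_wells = id[matrix_only],
         toxicity_only_wells = id[toxicity_only],
         both_wells = id[both]),
    class = "qc_report"
  )
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(
    "<qc_report> %d wells: %d excluded (%d insufficient matrix only, %d toxicity only, %d both)\n",
    x$total_wells, x$excluded, x$matrix_only, x$toxicity_only, x$both))
  invisible(x)
}
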