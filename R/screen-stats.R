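# Robust Z-score hit calling against negative controls, composited across
# replicate screens, plus assay-credentialing statistics (Z'-factor, CV) and
# the fluorescent-labeling reagent calculators.

#' Negative-control location/scale statistics for one plate
#'
#' @param control_values alignment values of the plate's negative-control
#'   wells (QC-passing).
#' @param mad_scale multiplier applied to the MAD; 1 (default) uses the raw
#'   median absolute deviation, 1.4826 applies the normal-consistency factor.
#' @return a `control_stats` list with `median_n`, `mad_n`, `n_controls`.
#' @export
control_stats <- function(control_values, mad_scale = 1) {
  v <- control_values[!is.na(control_values)]
  if (length(v) < 2L) {
    stop_fibrescreen("need at least 2 negative-control values (got %d)",
                     length(v), class = "degenerate_control_error")
  }
  med <- stats::median(v)
  mad_n <- stats::median(abs(v - med)) * mad_scale
  structure(list(median_n = med, mad_n = mad_n, n_controls = length(v)),
            class = "control_stats")
}

#' Robust Z-score of a well alignment value
#'
#' `Z = (x - median_N) / MAD_N` where the median and MAD are taken over the
#' plate's negative-control wells.  Negative Z means alignment below the
#' negative-control median.  The MAD is used unscaled by default (no 1.4826
#' factor); see [control_stats()].
#'
#' @param x well alignment value(s).
#' @param controls a [control_stats()].
#' @return robust Z-score(s).
#' @export
robust_z <- function(x, controls) {
  stopifnot(inherits(controls, "control_stats"))
  if (controls$mad_n <= 0) {
    stop_fibrescreen(
      "degenerate negative controls: MAD is 0 over %d control wells",
      controls$n_controls, class = "degenerate_control_error"
    )
  }
  (x - controls$median_n) / controls$mad_n
}

#' Composite Z-score across replicate screens
#'
#' Arithmetic mean of the per-replicate robust Z-scores over valid
#' replicates; absent (NA) when fewer than `min_valid` replicates survive QC.
#'
#' @param z per-replicate robust Z values (NA = replicate excluded).
#' @param min_valid minimum valid replicates (default 2).
#' @return mean Z, or NA if too few valid replicates.
#' @export
composite_z <- function(z, min_valid = 2L) {
  v <- z[!is.na(z)]
  if (length(v) < min_valid) return(NA_real_)
  mean(v)
}

#' Call hits against a reference condition
#'
#' A (compound, concentration) condition is a hit iff its composite Z-score
#' is less than or equal to the reference condition's composite Z (inclusive
#' rule); each condition is judged independently, so a compound can be a hit
#' at one concentration only.
#'
#' @param table data.frame with columns `compound`, `concentration`,
#'   `composite_z` (NA rows are excluded conditions and never hits).
#' @param reference `c(compound, concentration)` of the reference inhibitor,
#'   e.g. `c("Y-27632", 1)`.
#' @return the table with logical `hit` column and a `reference_z` attribute.
#' @export
call_hits <- function(table, reference) {
  stopifnot(is.data.frame(table),
            all(c("compound", "concentration", "composite_z") %in% names(table)))
  if (nrow(table) == 0L) {
    table$hit <- logical(0)
    attr(table, "reference_z") <- NA_real_
    return(table)
  }
  ref <- table$compound == reference[1] &
    table$concentration == as.numeric(reference[2])
  if (!any(ref) || all(is.na(table$composite_z[ref]))) {
    stop_fibrescreen(
      "reference condition %s @ %s umol/L is missing or has no composite Z",
      reference[1], reference[2], class = "config_error"
    )
  }
  ref_z <- table$composite_z[ref][1]
  table$hit <- !is.na(table$composite_z) & table$composite_z <= ref_z
  attr(table, "reference_z") <- ref_z
  table
}

#' Rank screen conditions by composite Z-score
#'
#' Ascending composite Z (most negative = rank 1); ties broken by compound
#' name, then concentration.  Conditions without a composite Z sink to the
#' bottom unranked.
#'
#' @param table data.frame with `compound`, `concentration`, `composite_z`.
#' @return the table sorted, with a `rank` column (NA for invalid conditions).
#' @export
rank_conditions <- function(table) {
  stopifnot(is.data.frame(table),
            all(c("compound", "concentration", "composite_z") %in% names(table)))
  ord <- order(is.na(table$composite_z), table$composite_z,
               table$compound, table$concentration)
  out <- table[ord, , drop = FALSE]
  out$rank <- ifelse(is.na(out$composite_z), NA_integer_,
                     seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}

#' Count conditions that promoted vs suppressed alignment
#'
#' @param composite_z vector of composite Z-scores (NA = excluded).
#' @return list with `n_positive` (Z > 0), `n_negative` (Z < 0), `n_zero`,
#'   `n_excluded`.
#' @export
sign_counts <- function(composite_z) {
  v <- composite_z
  list(n_positive = sum(!is.na(v) & v > 0),
       n_negative = sum(!is.na(v) & v < 0),
       n_zero = sum(!is.na(v) & v == 0),
       n_excluded = sum(is.na(v)))
}

#' Z'-factor: separation of positive and negative assay controls
#'
#' `Z' = 1 - 3 (sd_p + sd_n) / |mean_p - mean_n|`, with sample (n-1)
#' standard deviations.  Values above 0.5 indicate an excellent assay.
#'
#' @param pos,neg control value vectors (>= 2 each).
#' @return the Z'-factor.
#' @export
z_prime <- function(pos, neg) {
  if (length(pos) < 2L || length(neg) < 2L) {
    stop_fibrescreen("need at least 2 values per control group",
                     class = "parameter_error")
  }
  mu_p <- mean(pos); mu_n <- mean(neg)
  if (mu_p == mu_n) {
    stop_fibrescreen("control means are equal: separation undefined",
                     class = "undefined_separation_error")
  }
  1 - 3 * (stats::sd(pos) + stats::sd(neg)) / abs(mu_p - mu_n)
}

#' Coefficient of variation, in percent
#'
#' `100 * sd / mean` with the sample (n-1) standard deviation.
#'
#' @param values numeric vector with non-zero mean.
#' @return CV in percent.
#' @export
coefficient_of_variation <- function(values) {
  m <- mean(values)
  if (m == 0) {
    stop_fibrescreen("mean is zero: CV undefined", class = "parameter_error")
  }
  100 * stats::sd(values) / m
}

#' Shapiro-Wilk test on composite Z-scores
#'
#' Used to ask whether a screened library is skewed toward alignment
#' inhibitors (a significantly non-normal composite-Z distribution).
#' Delegates to [stats::shapiro.test()].
#'
#' @param composite_z numeric vector, 3 <= n <= 5000 after NA removal.
#' @return list with `statistic` (W) and `p_value`.
#' @export
distribution_skew_test <- function(composite_z) {
  v <- composite_z[!is.na(composite_z)]
  if (length(v) < 3L || length(v) > 5000L) {
    stop_fibrescreen("Shapiro-Wilk requires 3 <= n <= 5000 (got %d)",
                     length(v), class = "parameter_error")
  }
  t <- stats::shapiro.test(v)
  list(statistic = unname(t$statistic), p_value = t$p.value)
}

#' Absorbance reading for labeled-protein calculations
#'
#' @param A280,A494 path-length-corrected absorbances at 280 / 494 nm.
#' @param dilution dilution factor of the measured solution.
#' @param CF correction factor for dye absorbance at 280 nm (default 0.3 for
#'   NHS-fluorescein).
#' @param epsilon_protein molar extinction coefficient of the protein,
#'   1/(M cm) (default 677800, fibronectin).
#' @param epsilon_dye molar extinction coefficient of the dye, 1/(M cm)
#'   (default 68000, fluorescein).
#' @return an `absorbance_reading` list.
#' @export
absorbance_reading <- function(A280, A494, dilution = 1, CF = 0.3,
                               epsilon_protein = 677800, epsilon_dye = 68000) {
  if (A280 < 0 || A494 < 0) {
    stop_fibrescreen("absorbances must be non-negative", class = "parameter_error")
  }
  if (epsilon_protein <= 0 || epsilon_dye <= 0) {
    stop_fibrescreen("extinction coefficients must be positive",
                     class = "parameter_error")
  }
  structure(list(A280 = A280, A494 = A494, dilution = dilution, CF = CF,
                 epsilon_protein = epsilon_protein, epsilon_dye = epsilon_dye),
            class = "absorbance_reading")
}

#' Labeled-protein concentration from absorbance
#'
#' Molar concentration `= (A280 - CF * A494) / epsilon_protein * dilution`;
#' the dye's 280 nm contribution is removed via the correction factor.  Mass
#' concentration uses a configurable molecular weight (default 440 kDa for
#' fibronectin; the molar value is the primary quantity).
#'
#' @param reading an [absorbance_reading()].
#' @param molecular_weight protein molecular weight in g/mol (default 440000).
#' @return list with `molar` (mol/L) and `mg_per_ml`.
#' @export
protein_concentration <- function(reading, molecular_weight = 440000) {
  stopifnot(inherits(reading, "absorbance_reading"))
  corrected <- reading$A280 - reading$CF * reading$A494
  if (corrected < 0) {
    stop_fibrescreen(
      "A280 (%.4g) is below CF * A494 (%.4g): negative concentration",
      reading$A280, reading$CF * reading$A494, class = "parameter_error"
    )
  }
  molar <- corrected / reading$epsilon_protein * reading$dilution
  list(molar = molar, mg_per_ml = molar * molecular_weight)
}

#' Degree of labeling (dye molecules per protein molecule)
#'
#' `DOL = A494 / (epsilon_dye * protein_molar)`, for absorbance and molar
#' concentration referring to the same solution.
#'
#' @param reading an [absorbance_reading()].
#' @param protein_molar protein concentration in mol/L (> 0).
#' @return dimensionless labeling ratio.
#' @export
degree_of_labeling <- function(reading, protein_molar) {
  stopifnot(inherits(reading, "absorbance_reading"))
  if (protein_molar <= 0) {
    stop_fibrescreen("protein concentration must be positive",
                     class = "contract_error")
  }
  reading$A494 / (reading$epsilon_dye * protein_molar)
}

#' Reference hit table from the published kinase-inhibitor screen
#'
#' The top-27 conditions (compound, concentration, composite robust Z-score)
#' of a published 154-compound kinase-inhibitor matrix-alignment screen, as
#' printed in its hit table.  Used as a worked desk-scale input for
#' [call_hits()] and [rank_conditions()]: with reference Y-27632 at
#' 1 umol/L (Z = -0.98) all 27 conditions are hits, with H-9 at 10 umol/L
#' ranked first (Z = -1.97).
#'
#' @return data.frame with `rank`, `compound`, `concentration`,
#'   `composite_z`, `target`.
#' @export
kinase_screen_hits <- function() {
  path <- system.file("extdata", "kinase_screen_hits.csv",
                      package = "fibrescreen", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
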