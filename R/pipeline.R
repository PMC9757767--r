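# End-to-end screen analysis: FOV scoring -> QC cascade -> well aggregation ->
# per-plate robust Z -> composite Z across replicates -> hit calling.

#' Analyze a screen end to end
#'
#' Accepts either a [simulate_screen()] object (FOV stacks regenerated on
#' demand from the truth table) or a manifest (path or data.frame, see
#' [load_plate()]) whose `path` column names TIFF files relative to `dir`.
#'
#' For every FOV: maximum-intensity projection, background fraction and
#' insufficient-matrix flag, alignment scoring (structure tensor ->
#' mode-centered orientation histogram -> fraction within 20 degrees) on
#' unflagged FOV, and nuclei counting.  Wells are flagged for too few valid
#' FOV and for toxicity (< 40 percent of the plate's negative-control nuclei
#' baseline, computed over matrix-QC-passing control wells).  Per plate,
#' robust Z-scores are taken against the negative-control wells; composites
#' are averaged across replicates for conditions with at least
#' `min_valid_wells` valid wells.
#'
#' @param x a `sim_screen` object, a manifest data.frame, or a manifest CSV
#'   path.
#' @param dir directory for the manifest's relative TIFF paths.
#' @param config a [qc_config()].
#' @param gradient_sigma,window_sigma,weighting,min_energy_frac,halfwidth
#'   orientation-analysis settings (see [score_fov()]).
#' @param count_nuclei_channel set `FALSE` to skip nuclei counting (the
#'   toxicity rule is then inactive, as for plates acquired without a nuclei
#'   channel).
#' @param nucleus_radius nominal nucleus radius in px for [count_nuclei()]
#'   (taken from the simulator config when `x` is a `sim_screen`).
#' @param mad_scale MAD scaling for [control_stats()].
#' @param min_valid_wells minimum valid replicate wells per condition.
#' @return a `screen_result` list with `fov_table`, `well_table`,
#'   `condition_table` and `qc` (a [qc_report()]).
#' @export
analyze_screen <- function(x, dir = NULL, config = qc_config(),
                           gradient_sigma = 1, window_sigma = 2,
                           weighting = "energy_coherency",
                           min_energy_frac = 1e-4, halfwidth = 20,
                           count_nuclei_channel = TRUE, nucleus_radius = 8,
                           mad_scale = 1, min_valid_wells = 2L) {
  if (inherits(x, "sim_screen")) {
    manifest <- x$manifest
    sim_nuclei <- isTRUE(x$config$render_nuclei %||% TRUE)
    if (!sim_nuclei) count_nuclei_channel <- FALSE
    nucleus_radius <- x$config$nuclei_radius %||% nucleus_radius
    get_stack <- function(i) {
      simulate_fov(x$truth[i, ], shape = x$config$shape,
                   n_slices = x$config$n_slices, nuclei = sim_nuclei)
    }
    if (!is.null(x$dir)) {
      dir <- x$dir
      get_stack <- NULL
    }
  } else {
    manifest <- load_plate(x)$fovs
    get_stack <- NULL
  }
  if (is.null(get_stack)) {
    get_stack <- function(i) {
      p <- manifest$path[i]
      if (!is.null(dir)) p <- file.path(dir, p)
      read_fov_stack(p, well = manifest$well[i], fov_index = manifest$fov[i])
    }
  }

  n <- nrow(manifest)
  fov_table <- data.frame(
    plate = manifest$plate, well = manifest$well, fov = manifest$fov,
    compound = manifest$compound, concentration = manifest$concentration,
    role = manifest$role,
    background_fraction = NA_real_, flagged = NA,
    fraction_within_20 = NA_real_, mode_angle = NA_real_,
    total_weight = NA_real_, nuclei = NA_real_,
    stringsAsFactors = FALSE
  )
  for (i in seq_len(n)) {
    st <- get_stack(i)
    pr <- max_project(st)
    bf <- background_fraction(pr$matrix_mip, config$background_level)
    fl <- !is.null(flag_fov(bf, config))
    fov_table$background_fraction[i] <- bf
    fov_table$flagged[i] <- fl
    if (!fl) {
      sc <- score_fov(pr$matrix_mip, gradient_sigma, window_sigma,
                      weighting, min_energy_frac, halfwidth)
      fov_table$fraction_within_20[i] <- sc$fraction_within_20
      fov_table$mode_angle[i] <- sc$mode_angle
      fov_table$total_weight[i] <- sc$total_weight
    }
    if (count_nuclei_channel) {
      fov_table$nuclei[i] <- count_nuclei(pr$nuclei_mip,
                                          nucleus_radius = nucleus_radius)$count
    }
  }

  well_table <- aggregate_wells(fov_table, config)
  condition_table <- composite_conditions(well_table, mad_scale, min_valid_wells)
  structure(
    list(fov_table = fov_table, well_table = well_table,
         condition_table = condition_table,
         qc = qc_report(well_table),
         config = config),
    class = "screen_result"
  )
}

# Per-well aggregation and the well-level QC cascade.
aggregate_wells <- function(fov_table, config = qc_config()) {
  key <- paste(fov_table$plate, fov_table$well, sep = "\r")
  rows <- split(seq_len(nrow(fov_table)), key)
  wt <- do.call(rbind, lapply(rows, function(ii) {
    f <- fov_table[ii, ]
    data.frame(
      plate = f$plate[1], well = f$well[1], compound = f$compound[1],
      concentration = f$concentration[1], role = f$role[1],
      n_fov = nrow(f), n_valid_fov = sum(!f$flagged),
      nuclei = if (all(is.na(f$nuclei))) NA_real_ else mean(f$nuclei, na.rm = TRUE),
      alignment = if (sum(!f$flagged) >= config$min_valid_fov) {
        mean(f$fraction_within_20[!f$flagged])
      } else NA_real_,
      stringsAsFactors = FALSE
    )
  }))
  rownames(wt) <- NULL
  wt$matrix_fail <- wt$n_valid_fov < config$min_valid_fov
  # plate-wise nuclei baseline: negative controls passing matrix QC
  wt$nuclei_percent <- NA_real_
  for (p in unique(wt$plate)) {
    sel <- wt$plate == p
    ctrl <- sel & wt$role == "negative-control" & !wt$matrix_fail & !is.na(wt$nuclei)
    if (any(ctrl)) {
      baseline <- mean(wt$nuclei[ctrl])
      if (baseline > 0) {
        wt$nuclei_percent[sel] <- percent_of_control(wt$nuclei[sel], baseline)
      }
    }
  }
  wt$toxicity_fail <- !is.na(wt$nuclei_percent) &
    wt$nuclei_percent < config$min_nuclei_percent
  wt$excluded <- wt$matrix_fail | wt$toxicity_fail
  wt$exclusion_reason <- ifelse(
    wt$matrix_fail & wt$toxicity_fail, "insufficient_matrix+toxicity",
    ifelse(wt$matrix_fail, "insufficient_matrix",
           ifelse(wt$toxicity_fail, "toxicity", ""))
  )
  wt
}

# Robust Z per plate, composite across replicates, treatment-level QC.
composite_conditions <- function(well_table, mad_scale = 1, min_valid_wells = 2L) {
  wt <- well_table
  wt$z <- NA_real_
  for (p in unique(wt$plate)) {
    sel <- wt$plate == p
    ctrl_vals <- wt$alignment[sel & wt$role == "negative-control" & !wt$excluded]
    ctrl_vals <- ctrl_vals[!is.na(ctrl_vals)]
    if (length(ctrl_vals) < 2L) next
    cs <- control_stats(ctrl_vals, mad_scale = mad_scale)
    ok <- sel & !wt$excluded & !is.na(wt$alignment)
    wt$z[ok] <- robust_z(wt$alignment[ok], cs)
  }
  cond_key <- paste(wt$compound, wt$concentration, sep = "\r")
  groups <- split(seq_len(nrow(wt)), cond_key)
  ct <- do.call(rbind, lapply(groups, function(ii) {
    g <- wt[ii, ]
    zz <- g$z
    valid <- !g$excluded & !is.na(zz)
    data.frame(
      compound = g$compound[1], concentration = g$concentration[1],
      role = g$role[1], n_replicates = nrow(g),
      n_valid_replicates = sum(valid),
      composite_z = composite_z(zz[valid], min_valid = min_valid_wells),
      mean_alignment = if (any(valid)) mean(g$alignment[valid]) else NA_real_,
      stringsAsFactors = FALSE
    )
  }))
  rownames(ct) <- NULL
  ct
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("<screen_result> %d FOV, %d wells, %d conditions\n",
              nrow(x$fov_table), nrow(x$well_table), nrow(x$condition_table)))
  print(x$qc)
  invisible(x)
}

#' End-to-end hit-recovery experiment on simulated screens
#'
#' For each master seed, simulates a 3-replicate screen of `n_compounds` test
#' compounds of which `n_hits` carry planted anisotropy-reducing effects
#' (kappa multipliers 0.05-0.15, i.e. alignment-fraction reductions well past
#' the positive control's ~50 percent), runs the full analysis pipeline, and
#' calls hits against the planted positive-control reference (Y-27632 at
#' 10 umol/L).  Reports per-seed sensitivity (recovered planted hits) and
#' false positives (inert compounds called).
#'
#' @param master_seeds integer vector of master seeds (one screen each).
#' @param n_compounds,n_hits screen design (default 25 compounds, 5 planted).
#' @param shape FOV shape (default 256x256 px).
#' @param n_negative negative-control wells per plate.
#' @return data.frame with one row per seed: `sensitivity`,
#'   `false_positives`, `n_planted`, `n_inert`.
#' @export
recovery_experiment <- function(master_seeds, n_compounds = 25, n_hits = 5,
                                shape = c(256L, 256L), n_negative = 6) {
  planted <- sprintf("CPD-%02d", seq_len(n_hits))
  effects <- data.frame(
    compound = planted, concentration = 1,
    kappa_mult = seq(0.05, 0.15, length.out = n_hits),
    nuclei_mult = 1
  )
  rows <- lapply(master_seeds, function(ms) {
    cfg <- sim_screen_config(
      n_compounds = n_compounds, concentrations = 1, effects = effects,
      replicates = 3, n_negative = n_negative, n_positive = 1,
      shape = shape, render_nuclei = FALSE, master_seed = ms
    )
    res <- analyze_screen(simulate_screen(cfg))
    ht <- hit_table(res, c("Y-27632", 10))
    test_rows <- ht[!ht$compound %in% c("DMSO", "Y-27632"), ]
    is_planted <- test_rows$compound %in% planted
    data.frame(
      master_seed = ms,
      sensitivity = mean(test_rows$hit[is_planted]),
      false_positives = sum(test_rows$hit[!is_planted]),
      n_planted = sum(is_planted),
      n_inert = sum(!is_planted)
    )
  })
  do.call(rbind, rows)
}

#' Hit table from a screen result
#'
#' Calls and ranks hits against the reference condition; columns follow the
#' hit-table reading order (rank, compound, concentration, composite Z,
#' valid replicates, hit flag).
#'
#' @param result a `screen_result` (or a bare condition data.frame).
#' @param reference `c(compound, concentration)`, e.g. `c("Y-27632", 10)`.
#' @return ranked data.frame with `hit` column; `reference_z` attribute.
#' @export
hit_table <- function(result, reference) {
  ct <- if (inherits(result, "screen_result")) result$condition_table else result
  called <- call_hits(ct, reference)
  ranked <- rank_conditions(called)
  keep <- c("rank", "compound", "concentration", "composite_z",
            "n_valid_replicates", "hit")
  out <- ranked[, intersect(keep, names(ranked)), drop = FALSE]
  attr(out, "reference_z") <- attr(called, "reference_z")
  out
}
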