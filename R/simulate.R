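# Synthetic plate simulator: fibrous matrix fields with known orientation
# anisotropy, nuclei blobs with known counts, and planted per-compound
# effects, so the full pipeline is exercisable without microscope data.

#' Sample fiber orientations from an axial von Mises distribution
#'
#' Fiber orientation is axial (180-degree periodic), so angles are drawn from
#' a von Mises distribution on the full circle and halved: the doubled angle
#' `2*(theta - mean_angle)` is von Mises with concentration `kappa`.
#' `kappa = 0` reduces exactly to the uniform distribution on (-90, 90].
#'
#' @param n number of draws (>= 1).
#' @param kappa non-negative concentration parameter (0 = isotropic).
#' @param mean_angle mean orientation in degrees, (-90, 90].
#' @param seed optional integer seed.
#' @return `n` angles in degrees on (-90, 90].
#' @export
sample_orientations <- function(n, kappa, mean_angle = 0, seed = NULL) {
  if (n < 1) stop_fibrescreen("n must be >= 1", class = "parameter_error")
  if (kappa < 0) {
    stop_fibrescreen("kappa must be non-negative (got %g)", kappa,
                     class = "parameter_error")
  }
  if (!is.null(seed)) set.seed(seed)
  phi <- if (kappa == 0) {
    stats::runif(n, -pi, pi)
  } else {
    rvonmises(n, kappa)
  }
  wrap_orientation(mean_angle + phi * 90 / pi)
}

# Best & Fisher (1979) rejection sampler for von Mises(0, kappa) on (-pi, pi].
rvonmises <- function(n, kappa) {
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(16L, ceiling((n - length(out)) * 1.5))
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    ok <- (c0 * (2 - c0) - u2 > 0) | (log(c0 / u2) + 1 - c0 >= 0)
    th <- sign(u3[ok] - 0.5) * acos(f[ok])
    out <- c(out, th)
  }
  out[seq_len(n)]
}

#' Parameters of one synthetic fibrous-matrix field
#'
#' @param kappa orientation concentration (0 = isotropic).
#' @param mean_angle dominant orientation, degrees (-90, 90].
#' @param fiber_count number of fiber segments.
#' @param fiber_width_px,fiber_length_px segment geometry in px.
#' @param background_level camera background, a.u. (16-bit scale); the default
#'   50 a.u. sits below the 100 a.u. insufficient-matrix threshold.
#' @param diffuse_level diffuse (non-fibrillar) matrix signal added wherever
#'   matrix is present, a.u.; keeps healthy fields above the background
#'   threshold, as in real fibronectin lawns.
#' @param fiber_intensity peak per-fiber signal, a.u.
#' @param hole_fraction fraction of area covered by fibrillogenesis-failure
#'   holes (no matrix, background only), in [0, 1).
#' @param noise_sd Gaussian noise SD, a.u.
#' @param seed integer seed; identical params + seed give identical images.
#' @return a `fiber_field_params` list.
#' @export
fiber_field_params <- function(kappa = 3, mean_angle = 0, fiber_count = 300,
                               fiber_width_px = 3, fiber_length_px = NULL,
                               background_level = 50, diffuse_level = 300,
                               fiber_intensity = 2000, hole_fraction = 0,
                               noise_sd = 20, seed = 1L) {
  if (kappa < 0) stop_fibrescreen("kappa must be >= 0", class = "parameter_error")
  if (hole_fraction < 0 || hole_fraction >= 1) {
    stop_fibrescreen("hole_fraction must be in [0, 1)", class = "parameter_error")
  }
  if (fiber_intensity <= background_level) {
    stop_fibrescreen("fiber_intensity must exceed background_level",
                     class = "parameter_error")
  }
  if (noise_sd < 0) stop_fibrescreen("noise_sd must be >= 0", class = "parameter_error")
  structure(
    list(kappa = kappa, mean_angle = mean_angle,
         fiber_count = as.integer(fiber_count),
         fiber_width_px = fiber_width_px, fiber_length_px = fiber_length_px,
         background_level = background_level, diffuse_level = diffuse_level,
         fiber_intensity = fiber_intensity, hole_fraction = hole_fraction,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "fiber_field_params"
  )
}

# Rasterize anti-aliased straight segments; returns the noiseless fiber image.
# Scanline splat: walk the major axis one pixel at a time and lay an
# anti-aliased perpendicular profile across the minor axis.  Fluorescence is
# additive, so overlapping fibers sum, preserving edge gradients inside dense
# parallel bundles.
render_segments <- function(angles, H, W, length_px, width_px, intensity) {
  img <- matrix(0, H, W)
  half_len <- length_px / 2
  half_w <- width_px / 2
  cx <- stats::runif(length(angles), 1, W)
  cy <- stats::runif(length(angles), 1, H)
  for (i in seq_along(angles)) {
    th <- angles[i] * pi / 180
    ux <- cos(th); uy <- sin(th)          # unit vector along the fiber, y up
    if (abs(ux) >= abs(uy)) {
      # column-major walk: for each column, center row from the line equation
      x0 <- cx[i] - ux * half_len; x1 <- cx[i] + ux * half_len
      c0 <- max(1L, ceiling(min(x0, x1))); c1 <- min(W, floor(max(x0, x1)))
      if (c0 > c1) next
      cols <- c0:c1
      m <- length(cols)
      rc <- H + 1 - (cy[i] + (cols - cx[i]) * (uy / ux))  # fractional row
      span <- ceiling((half_w + 0.5) / abs(ux)) + 1L
      offs <- (-span):(span + 1L)
      rows_m <- outer(offs, floor(rc), `+`)
      d <- abs(rows_m - rep(rc, each = length(offs))) * abs(ux)
      prof <- pmin(pmax(half_w + 0.5 - d, 0), 1)
      ok <- rows_m >= 1L & rows_m <= H & prof > 0
      li <- rows_m[ok] + (rep(cols, each = length(offs))[ok] - 1L) * H
      img[li] <- img[li] + intensity * prof[ok]
    } else {
      # row-major walk for steep fibers
      y0 <- cy[i] - uy * half_len; y1 <- cy[i] + uy * half_len
      r0 <- max(1L, ceiling(H + 1 - max(y0, y1)))
      r1 <- min(H, floor(H + 1 - min(y0, y1)))
      if (r0 > r1) next
      rows <- r0:r1
      xc <- cx[i] + ((H + 1 - rows) - cy[i]) * (ux / uy)  # fractional col
      span <- ceiling((half_w + 0.5) / abs(uy)) + 1L
      offs <- (-span):(span + 1L)
      cols_m <- outer(offs, floor(xc), `+`)
      d <- abs(cols_m - rep(xc, each = length(offs))) * abs(uy)
      prof <- pmin(pmax(half_w + 0.5 - d, 0), 1)
      ok <- cols_m >= 1L & cols_m <= W & prof > 0
      li <- rep(rows, each = length(offs))[ok] + (cols_m[ok] - 1L) * H
      img[li] <- img[li] + intensity * prof[ok]
    }
  }
  img
}

# Z-slices as intensity-jittered copies of the clean field with independent
# noise, quantized to the unsigned 16-bit range.
make_slices <- function(clean, background_level, noise_sd, n_slices) {
  H <- nrow(clean); W <- ncol(clean)
  scales <- stats::runif(n_slices, 0.85, 1)
  v <- as.vector(clean) %o% scales + background_level
  if (noise_sd > 0) v <- v + stats::rnorm(length(v), 0, noise_sd)
  v <- round(v)
  v[v < 0] <- 0
  v[v > 65535] <- 65535
  dim(v) <- c(H, W, n_slices)
  v
}

# Circular holes of zero matrix covering >= hole_fraction of the image area.
render_holes <- function(H, W, hole_fraction) {
  mask <- matrix(FALSE, H, W)
  if (hole_fraction <= 0) return(mask)
  target <- hole_fraction * H * W
  rr <- matrix(seq_len(H), H, W)
  cc <- matrix(seq_len(W), H, W, byrow = TRUE)
  guard <- 0L
  while (sum(mask) < target && guard < 200L) {
    guard <- guard + 1L
    r <- stats::runif(1, 0.06, 0.14) * min(H, W)
    y <- stats::runif(1, 1, H); x <- stats::runif(1, 1, W)
    mask <- mask | ((rr - y)^2 + (cc - x)^2 <= r^2)
  }
  mask
}

#' Render the matrix channel of a synthetic field of view
#'
#' Straight anti-aliased fiber segments with orientations drawn from the
#' axial von Mises sampler sit on a diffuse matrix lawn; circular
#' fibrillogenesis-failure holes remove all matrix signal (lawn and fibers)
#' so the insufficient-matrix QC rule can fire.  Z-slices are intensity-
#' jittered copies of the clean field with independent noise, so the
#' maximum-intensity projection is meaningful.  Output is clipped to the
#' unsigned 16-bit range.
#'
#' @param params a [fiber_field_params()].
#' @param shape `c(rows, cols)`, at least 64x64.
#' @param n_slices number of z slices (default 9: 8 um depth at 1 um steps).
#' @return list with `stack` (rows x cols x n_slices), `clean` (noiseless
#'   field), `angles` (sampled fiber orientations) and `hole_mask`.
#' @export
render_fiber_fov <- function(params, shape = c(512L, 512L), n_slices = 9L) {
  stopifnot(inherits(params, "fiber_field_params"))
  if (any(shape < 64L)) {
    stop_fibrescreen("shape must be at least 64x64", class = "parameter_error")
  }
  H <- shape[1]; W <- shape[2]
  set.seed(params$seed)
  len <- params$fiber_length_px %||% (0.5 * min(H, W))
  angles <- if (params$fiber_count > 0) {
    sample_orientations(params$fiber_count, params$kappa, params$mean_angle)
  } else numeric(0)
  fibers <- if (length(angles)) {
    render_segments(angles, H, W, len, params$fiber_width_px,
                    params$fiber_intensity)
  } else matrix(0, H, W)
  holes <- render_holes(H, W, params$hole_fraction)
  clean <- (params$diffuse_level + fibers) * !holes
  stack <- make_slices(clean, params$background_level, params$noise_sd, n_slices)
  list(stack = stack, clean = clean, angles = angles, hole_mask = holes)
}

#' Render the nuclei channel of a synthetic field of view
#'
#' Gaussian-profile blobs (combined by maximum so overlapping nuclei keep
#' distinct peaks) at rejection-sampled centers.  Non-overlap is attempted
#' with a minimum separation of 2.2 radii; a configurable fraction of the
#' nuclei is instead placed as close pairs 1.2 radii apart to exercise
#' watershed splitting.
#'
#' @param count number of nuclei (>= 0).
#' @param radius_px nominal nucleus radius: the blob's full (3 sigma) extent.
#' @param seed integer seed.
#' @param shape `c(rows, cols)`.
#' @param overlap_fraction fraction of nuclei placed as 1.2-radius pairs.
#' @param intensity peak blob intensity, a.u.
#' @param background_level,noise_sd background model, a.u.
#' @param n_slices z slices (default 9).
#' @return list with `stack`, `centers` (data.frame row/col, ground truth).
#' @export
render_nuclei_fov <- function(count, radius_px = 8, seed = 1L,
                              shape = c(512L, 512L), overlap_fraction = 0,
                              intensity = 20000, background_level = 30,
                              noise_sd = 15, n_slices = 9L) {
  if (count < 0) stop_fibrescreen("count must be >= 0", class = "parameter_error")
  H <- shape[1]; W <- shape[2]
  set.seed(seed)
  margin <- 2 * radius_px
  n_pairs <- floor(count * overlap_fraction / 2)
  n_single <- count - 2L * n_pairs
  centers <- matrix(numeric(0), ncol = 2)
  min_sep <- 2.2 * radius_px
  place <- function(k_extra_sep) {
    attempts <- 0L
    repeat {
      attempts <- attempts + 1L
      if (attempts > 10000L) {
        stop_fibrescreen(
          "could not place %d non-overlapping nuclei in 10000 attempts", count,
          class = "placement_error"
        )
      }
      p <- c(stats::runif(1, margin, H - margin), stats::runif(1, margin, W - margin))
      if (nrow(centers) == 0) return(p)
      d <- sqrt((centers[, 1] - p[1])^2 + (centers[, 2] - p[2])^2)
      if (all(d >= min_sep + k_extra_sep)) return(p)
    }
  }
  if (count > 0) {
    for (i in seq_len(n_single)) centers <- rbind(centers, place(0))
    for (i in seq_len(n_pairs)) {
      # pair anchor needs clearance for its partner too
      a <- place(1.2 * radius_px)
      th <- stats::runif(1, 0, 2 * pi)
      b <- a + 1.2 * radius_px * c(cos(th), sin(th))
      centers <- rbind(centers, a, b)
    }
  }
  # Gaussian-profile blobs, combined by maximum so touching nuclei keep
  # distinct intensity peaks with a valley between them.  The nominal radius
  # is the blob's full extent (3 sigma): sharp enough that a 1.2-radius pair
  # stays bimodal after the counting pipeline's sigma = 2 blur.
  sigma <- radius_px / 3
  blob <- matrix(0, H, W)
  if (nrow(centers) > 0) {
    ext <- ceiling(4 * sigma)
    for (i in seq_len(nrow(centers))) {
      y <- centers[i, 1]; x <- centers[i, 2]
      rows <- max(1L, floor(H + 1 - y - ext)):min(H, ceiling(H + 1 - y + ext))
      cols <- max(1L, floor(x - ext)):min(W, ceiling(x + ext))
      d2 <- outer((H + 1 - rows - y)^2, (cols - x)^2, `+`)
      blob[rows, cols] <- pmax(blob[rows, cols],
                               intensity * exp(-d2 / (2 * sigma^2)))
    }
  }
  stack <- make_slices(blob, background_level, noise_sd, n_slices)
  centers_df <- if (nrow(centers)) {
    data.frame(row = H + 1 - centers[, 1], col = centers[, 2])
  } else data.frame(row = numeric(0), col = numeric(0))
  list(stack = stack, centers = centers_df)
}

#' Simulate one complete field of view (both channels)
#'
#' @param truth_row one row of a simulation truth table (see
#'   [simulate_screen()]).
#' @param shape image shape `c(rows, cols)`.
#' @param n_slices z slices.
#' @param nuclei render the nuclei channel (`FALSE` leaves it blank, for
#'   alignment-only experiments).
#' @return an [fov_stack()].
#' @export
simulate_fov <- function(truth_row, shape = c(512L, 512L), n_slices = 9L,
                         nuclei = TRUE) {
  p <- fiber_field_params(
    kappa = truth_row$kappa, mean_angle = truth_row$mean_angle,
    fiber_count = truth_row$fiber_count,
    background_level = truth_row$background_level,
    diffuse_level = truth_row$diffuse_level,
    fiber_intensity = truth_row$fiber_intensity,
    hole_fraction = truth_row$hole_fraction,
    noise_sd = truth_row$noise_sd, seed = truth_row$seed
  )
  mat <- render_fiber_fov(p, shape = shape, n_slices = n_slices)
  nuc_stack <- if (nuclei) {
    render_nuclei_fov(truth_row$nuclei_count,
                      radius_px = truth_row$nuclei_radius,
                      seed = truth_row$seed + 1L, shape = shape,
                      n_slices = n_slices)$stack
  } else {
    array(0, dim(mat$stack))
  }
  fov_stack(truth_row$well, truth_row$fov, mat$stack, nuc_stack)
}

#' Default configuration for a simulated screen
#'
#' Mirrors the screen design: replicate plates on separate days, a column of
#' negative-control (vehicle) wells, a positive-control condition with a
#' planted ~50 percent alignment reduction, and test compounds whose effects
#' are given by an effect table of multiplicative kappa (and optional nuclei)
#' factors.
#'
#' @param n_compounds number of test compounds (one concentration each unless
#'   `concentrations` given).
#' @param concentrations concentrations (umol/L) at which each compound is run.
#' @param effects data.frame with columns `compound`, `concentration`,
#'   `kappa_mult` in (0, 1] and optionally `nuclei_mult` (toxicity) and
#'   `hole_fraction` (fibrillogenesis failure); conditions absent from the
#'   table are inert.
#' @param replicates number of replicate plates (default 3).
#' @param n_negative,n_positive control wells per plate.
#' @param kappa_baseline anisotropy concentration of untreated (aligned)
#'   matrix.
#' @param positive_kappa_mult kappa multiplier of the positive-control
#'   condition (default tuned to roughly halve the alignment fraction).
#' @param nuclei_baseline mean nuclei per FOV.
#' @param shape FOV shape in px.
#' @param n_slices z slices per stack.
#' @param fiber_count,noise_sd,background_level,diffuse_level,fiber_intensity
#'   fiber-field parameters (see [fiber_field_params()]).
#' @param nuclei_radius nucleus radius in px.
#' @param render_nuclei render the nuclei channel (`FALSE` for
#'   alignment-only experiments; the toxicity filter is then inactive).
#' @param master_seed master seed; per-well seeds are derived from it with a
#'   counter-based scheme.
#' @return a config list for [simulate_screen()].
#' @export
sim_screen_config <- function(n_compounds = 4, concentrations = 1,
                              effects = NULL, replicates = 3,
                              n_negative = 8, n_positive = 1,
                              kappa_baseline = 2, positive_kappa_mult = 0.22,
                              nuclei_baseline = 60, shape = c(512L, 512L),
                              n_slices = 9L, fiber_count = 300, noise_sd = 20,
                              background_level = 50, diffuse_level = 300,
                              fiber_intensity = 2000, nuclei_radius = 8,
                              render_nuclei = TRUE, master_seed = 1L) {
  compounds <- sprintf("CPD-%02d", seq_len(n_compounds))
  if (is.null(effects)) {
    effects <- data.frame(compound = character(0), concentration = numeric(0),
                          kappa_mult = numeric(0), nuclei_mult = numeric(0))
  }
  if (!"nuclei_mult" %in% names(effects)) effects$nuclei_mult <- rep(1, nrow(effects))
  if (!"hole_fraction" %in% names(effects)) effects$hole_fraction <- rep(0, nrow(effects))
  unknown <- setdiff(effects$compound, compounds)
  if (length(unknown)) {
    stop_fibrescreen("effect table names compound(s) absent from the layout: %s",
                     paste(unknown, collapse = ", "), class = "config_error")
  }
  list(compounds = compounds, concentrations = concentrations,
       effects = effects, replicates = replicates,
       n_negative = n_negative, n_positive = n_positive,
       kappa_baseline = kappa_baseline,
       positive_kappa_mult = positive_kappa_mult,
       nuclei_baseline = nuclei_baseline, shape = shape, n_slices = n_slices,
       fiber_count = fiber_count, noise_sd = noise_sd,
       background_level = background_level, diffuse_level = diffuse_level,
       fiber_intensity = fiber_intensity, nuclei_radius = nuclei_radius,
       render_nuclei = render_nuclei, master_seed = master_seed)
}

#' Simulate a multi-plate screen
#'
#' Builds the plate layouts, the per-FOV ground-truth table (kappa, planted
#' effect, nuclei count, seeds) and the manifest.  With `out_dir` set, every
#' FOV TIFF plus `manifest.csv` and `truth.csv` are written to disk;
#' otherwise images are regenerated on demand from the truth table (the
#' generator is deterministic in the derived seeds), which keeps large
#' simulated screens in memory-free streaming form.
#'
#' @param config list from [sim_screen_config()].
#' @param out_dir optional output directory for TIFFs + manifest + truth.
#' @return a `sim_screen` object with `manifest`, `truth`, `config` and
#'   (if written) `dir`.
#' @export
simulate_screen <- function(config, out_dir = NULL) {
  cfg <- config
  conditions <- expand.grid(compound = cfg$compounds,
                            concentration = cfg$concentrations,
                            stringsAsFactors = FALSE)
  addresses <- well_addresses_384()
  truth <- list(); manifest <- list()
  for (r in seq_len(cfg$replicates)) {
    plate_id <- sprintf("plate%d", r)
    roles <- c(rep("negative-control", cfg$n_negative),
               rep("positive-control", cfg$n_positive),
               rep("test", nrow(conditions)))
    compounds <- c(rep("DMSO", cfg$n_negative),
                   rep("Y-27632", cfg$n_positive),
                   conditions$compound)
    concs <- c(rep(0, cfg$n_negative), rep(10, cfg$n_positive),
               conditions$concentration)
    n_wells <- length(roles)
    if (n_wells > 384L) {
      stop_fibrescreen("layout needs %d wells; a 384-well plate has 384",
                       n_wells, class = "config_error")
    }
    wells <- addresses[seq_len(n_wells)]
    for (wi in seq_len(n_wells)) {
      kmult <- 1; nmult <- 1; holes <- 0
      if (roles[wi] == "positive-control") kmult <- cfg$positive_kappa_mult
      if (roles[wi] == "test" && nrow(cfg$effects) > 0) {
        hit <- cfg$effects$compound == compounds[wi] &
          cfg$effects$concentration == concs[wi]
        if (any(hit)) {
          kmult <- cfg$effects$kappa_mult[hit][1]
          nmult <- cfg$effects$nuclei_mult[hit][1]
          holes <- cfg$effects$hole_fraction[hit][1]
        }
      }
      wseed <- derive_seed(cfg$master_seed, r, wi)
      set.seed(wseed)
      mean_angle <- stats::runif(1, -90, 90)
      n_nuc <- stats::rpois(1, cfg$nuclei_baseline * nmult)
      for (fv in 1:4) {
        truth[[length(truth) + 1L]] <- data.frame(
          plate = plate_id, replicate = r, well = wells[wi], fov = fv,
          compound = compounds[wi], concentration = concs[wi],
          role = roles[wi], kappa = cfg$kappa_baseline * kmult,
          kappa_mult = kmult, nuclei_mult = nmult,
          mean_angle = mean_angle,
          # constant areal fiber density across resolutions (512 px reference)
          fiber_count = round(cfg$fiber_count * min(cfg$shape) / 512),
          background_level = cfg$background_level,
          diffuse_level = cfg$diffuse_level,
          fiber_intensity = cfg$fiber_intensity,
          hole_fraction = holes, noise_sd = cfg$noise_sd,
          nuclei_count = n_nuc, nuclei_radius = cfg$nuclei_radius,
          seed = derive_seed(wseed, fv),
          stringsAsFactors = FALSE
        )
        manifest[[length(manifest) + 1L]] <- data.frame(
          plate = plate_id, replicate = r, well = wells[wi], fov = fv,
          path = sprintf("%s_%s_fov%d.tif", plate_id, wells[wi], fv),
          compound = compounds[wi], concentration = concs[wi],
          role = roles[wi], stringsAsFactors = FALSE
        )
      }
    }
  }
  truth <- do.call(rbind, truth)
  manifest <- do.call(rbind, manifest)
  out <- structure(list(manifest = manifest, truth = truth, config = cfg,
                        dir = out_dir),
                   class = "sim_screen")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(nrow(truth))) {
      st <- simulate_fov(truth[i, ], shape = cfg$shape,
                         n_slices = cfg$n_slices,
                         nuclei = isTRUE(cfg$render_nuclei %||% TRUE))
      write_fov_stack(st, file.path(out_dir, manifest$path[i]))
    }
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
    utils::write.csv(truth, file.path(out_dir, "truth.csv"), row.names = FALSE)
  }
  out
}

#' @export
print.sim_screen <- function(x, ...) {
  cat(sprintf("<sim_screen> %d plates, %d wells, %d FOV images%s\n",
              length(unique(x$manifest$plate)),
              nrow(unique(x$manifest[, c("plate", "well")])),
              nrow(x$manifest),
              if (is.null(x$dir)) " (in-memory, regenerated on demand)"
              else paste0(" in ", x$dir)))
  invisible(x)
}
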