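# Fiber-orientation analysis via the structure tensor.
#
# Conventions: images are matrices [row, col]; x runs along columns and y
# points *up* (toward decreasing row index), so angles are measured
# counter-clockwise from the image x axis, in degrees on (-90, 90].  A
# vertical stripe pattern (intensity varying along x) has fiber axis 90 deg.

# 1-D Gaussian (or Gaussian-derivative) kernel, radius 4*sigma.
gaussian_kernel <- function(sigma, deriv = 0L) {
  r <- max(1L, ceiling(4 * sigma))
  u <- (-r):r
  g <- exp(-u^2 / (2 * sigma^2))
  g <- g / sum(g)
  if (deriv == 0L) return(g)
  k <- -u / sigma^2 * g
  # normalize so the response to a unit-slope ramp is exactly 1
  k / sum(-u * k)
}

# Separable convolution with replicate boundary, as a banded-matrix product.
# B[i, j] = sum of kernel taps whose (clipped) source index is j.
conv_band_matrix <- function(n, kernel) {
  r <- (length(kernel) - 1L) %/% 2L
  B <- matrix(0, n, n)
  i <- seq_len(n)
  for (t in seq_along(kernel)) {
    j <- pmin(pmax(i + (t - r - 1L), 1L), n)
    B[cbind(i, j)] <- B[cbind(i, j)] + kernel[t]
  }
  B
}

# Band matrices are reused heavily across FOVs of one screen; cache them.
.band_cache <- new.env(parent = emptyenv())

cached_band <- function(n, kernel) {
  key <- sprintf("%d|%s", n, paste(signif(kernel, 12), collapse = ","))
  b <- .band_cache[[key]]
  if (is.null(b)) {
    b <- conv_band_matrix(n, kernel)
    if (length(ls(.band_cache)) > 32L) rm(list = ls(.band_cache),
                                          envir = .band_cache)
    .band_cache[[key]] <- b
  }
  b
}

# Filter rows (along y / dim 1) and columns (along x / dim 2) separably.
sep_filter <- function(img, krow, kcol) {
  Br <- cached_band(nrow(img), krow)
  Bc <- cached_band(ncol(img), kcol)
  Br %*% img %*% t(Bc)
}

#' Structure tensor of a projected matrix image
#'
#' Image gradients are taken with Gaussian-derivative filters at
#' `gradient_sigma`; the gradient products are then smoothed with a Gaussian
#' window at `window_sigma`, giving per-pixel tensor components `Jxx`, `Jxy`,
#' `Jyy`.  Per-pixel fiber orientation (perpendicular to the dominant gradient
#' direction), energy `E = Jxx + Jyy` and coherency
#' `C = sqrt((Jxx - Jyy)^2 + 4 Jxy^2) / E` are derived from the tensor.
#' The image is converted to floating point before analysis.
#'
#' @param image 2-D intensity matrix, at least 16x16.
#' @param gradient_sigma Gaussian-derivative scale in px (default 1).
#' @param window_sigma tensor smoothing window in px (default 2).
#' @return a `structure_tensor_field` list with matrices `Jxx`, `Jxy`, `Jyy`,
#'   `orientation` (deg, (-90, 90]), `energy`, `coherency`, and the sigmas.
#' @export
structure_tensor <- function(image, gradient_sigma = 1, window_sigma = 2) {
  if (!is.matrix(image) || nrow(image) < 16L || ncol(image) < 16L) {
    stop_fibrescreen("image must be a matrix of at least 16x16 px",
                     class = "contract_error")
  }
  if (gradient_sigma <= 0 || window_sigma <= 0) {
    stop_fibrescreen("sigmas must be positive", class = "parameter_error")
  }
  img <- matrix(as.double(image), nrow(image), ncol(image))
  g  <- gaussian_kernel(gradient_sigma, 0L)
  dg <- gaussian_kernel(gradient_sigma, 1L)
  # d/dx: derivative along columns; d/dy: along rows with y pointing up,
  # i.e. the negated derivative along increasing row index.
  gx <- sep_filter(img, g, dg)
  gy <- -sep_filter(img, dg, g)
  w <- gaussian_kernel(window_sigma, 0L)
  Jxx <- sep_filter(gx * gx, w, w)
  Jxy <- sep_filter(gx * gy, w, w)
  Jyy <- sep_filter(gy * gy, w, w)
  # numerical guard: smoothing of products keeps Jxx, Jyy >= 0 up to rounding
  Jxx[Jxx < 0] <- 0
  Jyy[Jyy < 0] <- 0
  E <- Jxx + Jyy
  theta_grad <- 0.5 * atan2(2 * Jxy, Jxx - Jyy) * 180 / pi
  orientation <- wrap_orientation(theta_grad + 90)
  C <- matrix(0, nrow(img), ncol(img))
  pos <- E > 0
  C[pos] <- sqrt((Jxx[pos] - Jyy[pos])^2 + 4 * Jxy[pos]^2) / E[pos]
  structure(
    list(Jxx = Jxx, Jxy = Jxy, Jyy = Jyy,
         orientation = orientation, energy = E, coherency = C,
         gradient_sigma = gradient_sigma, window_sigma = window_sigma,
         intensity_scale = max(abs(img))),
    class = "structure_tensor_field"
  )
}

#' Orientation histogram from a structure-tensor field
#'
#' 180 one-degree bins with centers at the integers -89..90 degrees; a pixel
#' whose orientation falls in (-90, -89.5] wraps into the 90-degree bin.
#' Pixels with energy above `min_energy_frac * max(energy)` contribute a
#' weight of `energy * coherency` (default), `energy`, or 1 (`"unit"`), and
#' the histogram is normalized to sum to 1.
#'
#' @param field a `structure_tensor_field`.
#' @param weighting `"energy_coherency"`, `"energy"`, or `"unit"`.
#' @param min_energy_frac minimum-energy floor as a fraction of the maximum
#'   pixel energy.
#' @return an `orientation_histogram` with `centers` (-89..90), `weights`
#'   (sum 1), `mode_angle`, `total_weight` (pre-normalization energy) and
#'   `centered` flag.
#' @export
orientation_histogram <- function(field,
                                  weighting = c("energy_coherency", "energy", "unit"),
                                  min_energy_frac = 1e-4) {
  stopifnot(inherits(field, "structure_tensor_field"))
  weighting <- match.arg(weighting)
  emax <- max(field$energy)
  # energy at or below numerical dust relative to the intensity scale means a
  # constant image: no orientation content
  scale <- field$intensity_scale %||% 1
  if (emax <= (1e-9 * max(scale, .Machine$double.eps))^2) {
    stop_fibrescreen("zero-energy image: orientation histogram undefined",
                     class = "zero_energy_error")
  }
  keep <- field$energy > min_energy_frac * emax
  if (!any(keep)) {
    stop_fibrescreen("no pixels above the minimum-energy floor",
                     class = "zero_energy_error")
  }
  th <- field$orientation[keep]
  w <- switch(weighting,
    energy_coherency = field$energy[keep] * field$coherency[keep],
    energy = field$energy[keep],
    unit = rep(1, sum(keep))
  )
  idx <- as.integer(round(th))
  idx[idx == -90L] <- 90L        # wrap (-90, -89.5] into the 90-deg bin
  weights <- numeric(180L)
  sums <- rowsum(w, idx)         # fast weighted binning, sorted unique idx
  weights[as.integer(rownames(sums)) + 90L] <- sums[, 1]
  total <- sum(weights)
  if (total <= 0) {
    stop_fibrescreen("all qualifying pixels carry zero weight",
                     class = "zero_energy_error")
  }
  new_orientation_histogram(weights / total, total_weight = total)
}

new_orientation_histogram <- function(weights, total_weight = sum(weights),
                                      centered = FALSE, tie = FALSE) {
  centers <- -89:90
  mode_idx <- which(weights == max(weights))
  tie <- tie || length(mode_idx) > 1L
  mode_angle <- min(centers[mode_idx])   # ties broken toward the smaller angle
  structure(
    list(centers = centers, weights = as.numeric(weights),
         mode_angle = mode_angle, total_weight = total_weight,
         centered = centered, mode_tie = tie),
    class = "orientation_histogram"
  )
}

#' Build an orientation histogram from raw weights
#'
#' Constructor for a pre-binned 180-bin angular distribution (bin centers
#' -89..90 degrees); weights are normalized to sum to 1.
#'
#' @param weights non-negative numeric vector of length 180.
#' @return an `orientation_histogram`.
#' @export
as_orientation_histogram <- function(weights) {
  if (length(weights) != 180L || any(weights < 0) || sum(weights) <= 0) {
    stop_fibrescreen("weights must be 180 non-negative values with positive sum",
                     class = "parameter_error")
  }
  new_orientation_histogram(weights / sum(weights), total_weight = sum(weights))
}

#' @export
print.orientation_histogram <- function(x, ...) {
  cat(sprintf("<orientation_histogram> 180 x 1-deg bins, mode %d deg%s%s, fraction within 20 deg of mode %.3f\n",
              x$mode_angle,
              if (x$centered) " (centered)" else "",
              if (isTRUE(x$mode_tie)) " [tie, smallest angle taken]" else "",
              fraction_within(if (x$centered) x else center_at_mode(x))))
  invisible(x)
}

#' Center an orientation histogram at its mode
#'
#' Bins are circularly shifted on the 180-degree periodic domain so the modal
#' bin sits at 0 degrees; total weight is conserved exactly.  Tied maximal
#' bins are broken toward the smallest angle (and flagged via `mode_tie`).
#'
#' @param hist an `orientation_histogram`.
#' @return the centered histogram (`mode_angle` 0, `centered = TRUE`).
#' @export
center_at_mode <- function(hist) {
  stopifnot(inherits(hist, "orientation_histogram"))
  shift <- hist$mode_angle            # bin centers are integers
  pos <- match(shift, hist$centers)
  zero_pos <- match(0L, hist$centers)
  w <- hist$weights
  rot <- (seq_along(w) - 1L + (pos - zero_pos)) %% 180L + 1L
  out <- new_orientation_histogram(w[rot], total_weight = hist$total_weight,
                                   centered = TRUE, tie = hist$mode_tie)
  out$mode_angle <- 0L
  out
}

#' Fraction of fiber weight within a half-width of the mode
#'
#' On a mode-centered histogram, sums the normalized weights of all bins
#' whose centers lie within circular distance `halfwidth` (inclusive) of 0
#' degrees; with the default 20 degrees these are the 41 bins -20..20.
#' A perfectly uniform histogram gives 41/180 = 0.22778.
#'
#' @param hist a centered `orientation_histogram`.
#' @param halfwidth half-width in degrees, in (0, 90).
#' @return alignment fraction in [0, 1].
#' @export
fraction_within <- function(hist, halfwidth = 20) {
  stopifnot(inherits(hist, "orientation_histogram"))
  if (halfwidth <= 0 || halfwidth >= 90) {
    stop_fibrescreen("halfwidth must be in (0, 90) degrees",
                     class = "parameter_error")
  }
  if (!isTRUE(hist$centered)) {
    stop_fibrescreen("fraction_within requires a mode-centered histogram",
                     class = "contract_error")
  }
  d <- orientation_distance(hist$centers, 0)
  sum(hist$weights[d <= halfwidth])
}

#' Score one field of view: orientation histogram alignment statistic
#'
#' Runs structure tensor -> histogram -> mode centering -> fraction within
#' 20 degrees on a matrix-channel maximum-intensity projection.
#'
#' @param mip 2-D matrix-channel projection.
#' @param gradient_sigma,window_sigma structure-tensor scales (px).
#' @param weighting,min_energy_frac see [orientation_histogram()].
#' @param halfwidth alignment half-width in degrees.
#' @return list with `fraction_within_20`, `mode_angle`, `total_weight`.
#' @export
score_fov <- function(mip, gradient_sigma = 1, window_sigma = 2,
                      weighting = "energy_coherency", min_energy_frac = 1e-4,
                      halfwidth = 20) {
  st <- structure_tensor(mip, gradient_sigma, window_sigma)
  h <- orientation_histogram(st, weighting = weighting,
                             min_energy_frac = min_energy_frac)
  list(fraction_within_20 = fraction_within(center_at_mode(h), halfwidth),
       mode_angle = h$mode_angle,
       total_weight = h$total_weight)
}

#' Aggregate FOV alignment values into a well alignment value
#'
#' The well value is the arithmetic mean of the alignment fraction over the
#' unflagged fields of view; at least 3 of the 4 must have passed QC (wells
#' with 2 or more flagged FOV are excluded upstream).
#'
#' @param fractions numeric alignment fractions, one per FOV.
#' @param flagged logical QC flags, same length (TRUE = excluded FOV).
#' @return mean alignment over unflagged FOV.
#' @export
score_well <- function(fractions, flagged = rep(FALSE, length(fractions))) {
  stopifnot(length(fractions) == length(flagged))
  keep <- !flagged & !is.na(fractions)
  if (sum(keep) < 3L) {
    stop_fibrescreen(
      "well has only %d unflagged FOV; wells with fewer than 3 valid FOV must be excluded upstream",
      sum(keep), class = "contract_error"
    )
  }
  mean(fractions[keep])
}
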