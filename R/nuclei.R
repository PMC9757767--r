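# Nuclei counting from the Hoechst-channel projection, for the toxicity
# filter.  Standard image steps (Gaussian blur, Otsu threshold, distance
# transform, watershed, labelling) delegate to EBImage.

#' Count nuclei in a nuclei-channel projection
#'
#' Pipeline: Gaussian blur (sigma = 2 px) -> global threshold (Otsu by
#' default, on the blurred image rescaled to [0, 1]) -> intensity-guided
#' watershed to split touching nuclei -> connected labels counted.  The
#' watershed height map is the blurred intensity above threshold, normalized
#' to [0, 1], so two touching nuclei are split along the intensity valley
#' between their peaks (a distance-map-only watershed cannot separate pairs
#' whose thresholded union is convex, which Gaussian blur produces for
#' closely overlapping nuclei).  Objects smaller than the area of a circle of
#' one quarter the configured nucleus radius (about half the radius of a
#' thresholded blob) are discarded as watershed shards.  An all-background
#' image counts 0 nuclei (not an error).
#'
#' @param nuclei_mip 2-D nuclei-channel maximum-intensity projection (a.u.).
#' @param blur_sigma Gaussian blur scale in px (default 2).
#' @param threshold `"otsu"` or a fixed intensity in a.u.
#' @param nucleus_radius nominal nucleus radius in px; sets the minimum
#'   object-area floor and the watershed local-maximum neighbourhood.
#' @param watershed_tolerance minimum peak-to-valley depth, as a fraction of
#'   the above-threshold intensity range, for two basins to stay split.
#' @return a `nuclei_count` list with `count` and the integer `label_mask`
#'   (0 = background).
#' @export
count_nuclei <- function(nuclei_mip, blur_sigma = 2, threshold = "otsu",
                         nucleus_radius = 8, watershed_tolerance = 0.1) {
  if (length(nuclei_mip) == 0L) {
    stop_fibrescreen("empty projection", class = "contract_error")
  }
  img <- matrix(as.double(nuclei_mip), nrow(nuclei_mip), ncol(nuclei_mip))
  # EBImage images are [x, y]; our matrices are [row, col].  Counting and
  # areas are invariant to the transpose, so feed the matrix directly.
  sm <- EBImage::gblur(EBImage::Image(img / 65535), sigma = blur_sigma)
  thr <- if (identical(threshold, "otsu")) {
    rng <- range(sm)
    if (diff(rng) <= 0) return(nuclei_count_result(matrix(0L, nrow(img), ncol(img))))
    # Otsu on the blurred image rescaled to [0,1] (invariant to affine
    # intensity changes, so counts survive uniform rescaling)
    sc <- (sm - rng[1]) / diff(rng)
    EBImage::otsu(sc, range = c(0, 1)) * diff(rng) + rng[1]
  } else {
    threshold / 65535
  }
  mask <- sm > thr
  if (!any(mask)) return(nuclei_count_result(matrix(0L, nrow(img), ncol(img))))
  # normalized above-threshold height map: affine-invariant by construction
  hmax <- max(sm)
  height <- (sm - thr) / (hmax - thr)
  height[!mask] <- 0
  labels <- EBImage::watershed(EBImage::Image(height),
                               tolerance = watershed_tolerance,
                               ext = max(1L, round(nucleus_radius / 4)))
  lab <- EBImage::imageData(labels)
  # drop shards below the minimum-area floor
  min_area <- pi * (nucleus_radius / 4)^2
  sizes <- tabulate(lab[lab > 0])
  drop <- which(sizes > 0 & sizes < min_area)
  if (length(drop)) lab[lab %in% drop] <- 0L
  # relabel compactly
  kept <- sort(unique(lab[lab > 0]))
  relab <- matrix(0L, nrow(img), ncol(img))
  if (length(kept)) relab[] <- match(lab, kept, nomatch = 0L)
  nuclei_count_result(relab)
}

nuclei_count_result <- function(label_mask) {
  structure(
    list(count = length(setdiff(unique(as.integer(label_mask)), 0L)),
         label_mask = label_mask),
    class = "nuclei_count"
  )
}

#' @export
print.nuclei_count <- function(x, ...) {
  cat(sprintf("<nuclei_count> %d nuclei\n", x$count))
  invisible(x)
}

#' Percent-of-control nuclei
#'
#' @param well_count per-well mean FOV nuclei count.
#' @param control_baseline mean nuclei count of the plate's negative-control
#'   wells (must be positive).
#' @return `100 * well_count / control_baseline`.
#' @export
percent_of_control <- function(well_count, control_baseline) {
  if (is.na(control_baseline) || control_baseline <= 0) {
    stop_fibrescreen("control nuclei baseline must be positive",
                     class = "contract_error")
  }
  100 * well_count / control_baseline
}
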