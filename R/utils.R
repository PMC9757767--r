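#' Wrap angles to the axial orientation domain (-90, 90]
#'
#' Fiber orientation is axial: an angle and its 180-degree rotation describe
#' the same fiber.  All orientations in this package live on (-90, 90] degrees.
#'
#' @param a numeric vector of angles in degrees.
#' @return angles wrapped to (-90, 90].
#' @export
wrap_orientation <- function(a) {
  r <- ((a + 90) %% 180) - 90
  r[r <= -90] <- r[r <= -90] + 180
  r
}

#' Circular distance on the 180-degree orientation domain
#'
#' @param a,b angles in degrees.
#' @return elementwise distance in degrees, in [0, 90].
#' @export
orientation_distance <- function(a, b) {
  d <- abs(wrap_orientation(a) - wrap_orientation(b)) %% 180
  pmin(d, 180 - d)
}

# Counter-based derivation of per-entity seeds from one master seed.  Keeps
# well-level streams independent and reproducible; result stays below 2^31.
derive_seed <- function(master, ...) {
  idx <- c(...)
  s <- as.double(master) %% 2147483647
  for (k in idx) {
    s <- (s * 48271 + as.double(k) * 9973 + 1) %% 2147483647
  }
  as.integer(s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_fibrescreen <- function(fmt, ..., class) {
  stop(structure(
    class = c(class, "fibrescreen_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}
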