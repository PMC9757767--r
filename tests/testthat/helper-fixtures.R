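# Test fixtures and independent oracles, built in code.

# Sinusoidal stripe pattern whose FIBER axis lies along angle_deg (degrees,
# counter-clockwise from the x axis, y up).  Intensity varies along the
# perpendicular direction.
stripe_image <- function(angle_deg, n = 64, period = 8, amplitude = 1000,
                         offset = 2000) {
  th <- angle_deg * pi / 180
  px <- matrix(seq_len(n), n, n, byrow = TRUE)   # x = column
  py <- matrix(seq(n, 1), n, n)                  # y points up
  phase <- -sin(th) * px + cos(th) * py          # perpendicular coordinate
  offset + amplitude * sin(2 * pi * phase / period)
}

# Bilinear rotation of a square image about its center by phi degrees
# (counter-clockwise, y up); out-of-range samples take the image mean.
rotate_bilinear <- function(img, phi_deg) {
  n <- nrow(img)
  stopifnot(ncol(img) == n)
  phi <- phi_deg * pi / 180
  ctr <- (n + 1) / 2
  out <- matrix(mean(img), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  rows <- matrix(seq_len(n), n, n)
  x <- cols - ctr
  y <- (n + 1 - rows) - ctr
  # inverse map: source coords = R(-phi) %*% (x, y)
  sx <- cos(phi) * x + sin(phi) * y + ctr
  sy <- -sin(phi) * x + cos(phi) * y + ctr
  sr <- (n + 1) - sy                              # back to row coordinate
  x0 <- floor(sx); r0 <- floor(sr)
  fx <- sx - x0; fr <- sr - r0
  ok <- x0 >= 1 & x0 + 1 <= n & r0 >= 1 & r0 + 1 <= n
  idx <- function(r, c) (c - 1L) * n + r
  v <- (1 - fx[ok]) * (1 - fr[ok]) * img[idx(r0[ok], x0[ok])] +
    fx[ok] * (1 - fr[ok]) * img[idx(r0[ok], x0[ok] + 1L)] +
    (1 - fx[ok]) * fr[ok] * img[idx(r0[ok] + 1L, x0[ok])] +
    fx[ok] * fr[ok] * img[idx(r0[ok] + 1L, x0[ok] + 1L)]
  out[ok] <- v
  out
}

# Brute-force per-pixel maximum projection (triple loop).
loop_max_project <- function(stack) {
  d <- dim(stack)
  out <- matrix(-Inf, d[1], d[2])
  for (r in seq_len(d[1])) {
    for (c in seq_len(d[2])) {
      m <- stack[r, c, 1]
      for (k in seq_len(d[3])) if (stack[r, c, k] > m) m <- stack[r, c, k]
      out[r, c] <- m
    }
  }
  out
}

# Brute-force per-pixel orientation histogram from a structure-tensor field:
# scalar loop recomputing orientation, energy, coherency and the bin index.
loop_orientation_histogram <- function(field, weighting = "energy_coherency",
                                       min_energy_frac = 1e-4) {
  w <- numeric(180)
  emax <- max(field$Jxx + field$Jyy)
  floor_e <- min_energy_frac * emax
  for (r in seq_len(nrow(field$Jxx))) {
    for (c in seq_len(ncol(field$Jxx))) {
      jxx <- field$Jxx[r, c]; jxy <- field$Jxy[r, c]; jyy <- field$Jyy[r, c]
      e <- jxx + jyy
      if (e <= floor_e) next
      th <- 0.5 * atan2(2 * jxy, jxx - jyy) * 180 / pi + 90
      if (th > 90) th <- th - 180
      if (th <= -90) th <- th + 180
      coh <- sqrt((jxx - jyy)^2 + 4 * jxy^2) / e
      wt <- switch(weighting,
                   energy_coherency = e * coh,
                   energy = e,
                   unit = 1)
      b <- round(th)
      if (b == -90) b <- 90
      w[b + 90] <- w[b + 90] + wt
    }
  }
  w / sum(w)
}

# One small in-memory simulated screen shared by several tests.
tiny_screen <- function(master_seed = 11L, effects = NULL, n_compounds = 2,
                        shape = c(128L, 128L), replicates = 3,
                        render_nuclei = FALSE, nuclei_baseline = 20, ...) {
  cfg <- sim_screen_config(
    n_compounds = n_compounds, concentrations = 1, effects = effects,
    replicates = replicates, n_negative = 4, n_positive = 1,
    shape = shape, nuclei_baseline = nuclei_baseline,
    render_nuclei = render_nuclei, master_seed = master_seed, ...
  )
  simulate_screen(cfg)
}
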