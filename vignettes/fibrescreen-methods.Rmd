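---
title: "Methods: scoring ECM fiber alignment in high-throughput screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring ECM fiber alignment in high-throughput screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibrescreen)
```

## The assay and what this package computes

Cancer-associated fibroblasts remodel the extracellular matrix (ECM) from a
randomly oriented (isotropic) mesh into aligned, anisotropic fiber tracks
that promote tumor cell invasion.  Cell-derived matrices (CDM) grown in
384-well plates reproduce this phenotype in vitro, and a screen asks which
compounds *normalize* an aligned matrix back toward isotropy.  The raw data
are two-channel confocal z-stacks (fluorescent fibronectin matrix + Hoechst
nuclei), 4 fields of view (FOV) per well, 8 µm depth at 1 µm steps
(9 slices), repeated on 3 replicate plates.

`fibrescreen` implements the full analysis chain:

1. **Projection.** Each stack is reduced by a per-pixel maximum-intensity
   projection (`max_project()`).
2. **Orientation.** A structure tensor gives per-pixel fiber orientation,
   energy and coherency; pixel weights are binned into a 180 × 1° histogram,
   the histogram is circularly centered at its mode, and the **alignment
   value** of the FOV is the weight fraction within ±20° of the mode
   (`structure_tensor()`, `orientation_histogram()`, `center_at_mode()`,
   `fraction_within()`).  A perfectly uniform histogram scores exactly
   41/180 ≈ 0.228 (41 one-degree bins lie within the inclusive ±20° window).
3. **QC cascade.** FOVs with more than 10 % of pixels at or below the
   100 a.u. background level are flagged (insufficient matrix / imaging
   error); wells with ≥ 2 flagged FOVs (of 4) are excluded; wells with
   < 40 % of the control nuclei count are excluded for toxicity; conditions
   with ≥ 2 excluded replicate wells are dropped from the hit list.
4. **Hit calling.** Per plate, a robust Z-score
   `Z = (x − median_N) / MAD_N` is computed against the negative-control
   wells (unscaled MAD, see below); Z-scores are averaged across valid
   replicates into a composite; conditions are ranked ascending and called
   hits when their composite is ≤ the reference inhibitor's composite
   (inclusive rule, each concentration judged independently).
5. **Credentialing.** `z_prime()` and `coefficient_of_variation()` implement
   the standard assay-quality statistics, and `distribution_skew_test()`
   (Shapiro–Wilk, delegated to `stats::shapiro.test`) asks whether a
   library's composite Z distribution is skewed toward inhibitors.

## Orientation estimation in detail

Images are converted to floating point.  Gradients are Gaussian-derivative
filters at `gradient_sigma = 1` px; the products `gx²`, `gx·gy`, `gy²` are
smoothed with a Gaussian window at `window_sigma = 2` px to form the tensor
(Jxx, Jxy, Jyy).  The fiber orientation is perpendicular to the dominant
gradient direction, `θ = ½·atan2(2Jxy, Jxx − Jyy) + 90°`, wrapped to
(−90°, 90°], with x along image columns and y pointing up.  Energy is
`E = Jxx + Jyy` and coherency `C = √((Jxx−Jyy)² + 4Jxy²)/E`.

The upstream tool this stage replaces does not document which weighting its
histogram uses, so the weighting is an explicit config choice: each pixel
above a minimum-energy floor (`1e-4 ×` the maximum pixel energy) contributes
`E·C` (default), `E`, or `1` to its 1° bin.  `E·C` is the default because it
suppresses both flat background (low E) and isotropic junctions (low C),
which stabilizes the mode on fibrous textures; the package's oracle tests
check all three weightings against a per-pixel loop.

Conventions that matter for exactness:

* Bins are centered on the integers −89…90; an orientation in (−90, −89.5]
  wraps into the 90° bin.  "Within 20 degrees" is inclusive, so the uniform
  histogram scores exactly 41/180.
* Tied modes are broken toward the smaller angle and flagged
  (`mode_tie`) — deterministic, and measure-zero on real data.
* Mode centering is a pure circular shift: weight is conserved exactly.
* The boundary condition of the separable convolutions is edge replication.

## Robust statistics

The MAD denominator is used **unscaled** — the screen statistic is defined as
the median of absolute deviations itself, not a normal-consistent standard
deviation estimate.  `control_stats(..., mad_scale = 1.4826)` restores the
consistency factor for users who want σ-scaled Z-scores; every Z in one
analysis uses one convention, so hit *ranking* is unaffected by the choice,
and the hit *threshold* is too because the reference condition is scored with
the same denominator.  Negative-control pools are per plate, so plate-level
drift cancels.  `MAD = 0` (degenerate controls) is an error, not a silent
division.

Z′ and CV use sample (n−1) standard deviations, the convention for small
control groups.

## Nuclei counting

The toxicity filter needs nuclei counts per FOV: Gaussian blur (σ = 2 px) →
global Otsu threshold on the blurred image rescaled to [0, 1] (making counts
invariant to uniform intensity changes) → watershed → labeled objects, with
a minimum-area floor (circle of ¼ the nominal nucleus radius) to suppress
shards.  Percent-of-control uses the mean count over the same plate's
negative-control wells that passed matrix QC, so controls average 100 % by
construction and plate effects cancel.

One design choice deviates from the obvious default and deserves a note: the
watershed runs on the **blurred intensity** (normalized above threshold),
not on the distance transform of the mask.  With a σ = 2 blur and a global
threshold, two nuclei ~1.2 radii apart threshold to a *convex* blob — there
is no distance-map saddle left to cut, so a distance-transform watershed
cannot ever separate them.  The intensity valley between the two peaks does
survive blurring, and splitting along it is robust (the test suite
constructs exactly this geometry).  The EBImage watershed's maximum
neighborhood is `radius/4` (larger neighborhoods merge the paired peaks) and
the tolerance is 0.1 of the above-threshold range, which is scale-free.

## The synthetic plate simulator

Every stage above is exercised without microscope data by
`simulate_screen()`, which emulates:

* **Fibrous texture.** Straight anti-aliased segments (length 0.5 × image
  side, width 3 px) with orientations drawn from an axial von Mises
  distribution: the doubled angle is von Mises with concentration κ, so
  κ = 0 is exactly uniform on the 180° domain and large κ collapses onto the
  mean angle.  Fluorescence is additive, so overlapping fibers sum — this
  preserves edge gradients inside dense parallel bundles, which is what the
  structure tensor reads.
* **Intensity model.** Camera background 50 a.u. + a diffuse matrix lawn
  (300 a.u.) wherever matrix is present + fibers (2000 a.u. peak) + Gaussian
  noise (SD 20 a.u.), quantized to unsigned 16-bit.  A healthy FOV therefore
  sits safely above the 100 a.u. QC threshold, while fibrillogenesis-failure
  *holes* (random discs with all matrix signal removed) fall below it, and a
  50 % hole fraction trips the >10 % background rule by a wide margin.
* **Z-stacks.** Slices are intensity-jittered copies (0.85–1.0×) of the
  clean field with independent noise, so maximum projection is meaningful
  without simulating optics.
* **Nuclei.** Gaussian-profile blobs (nominal radius = full 3σ extent,
  default 8 px) at rejection-sampled centers with ≥ 2.2 radii separation; a
  configurable fraction is instead placed as 1.2-radius pairs to exercise
  watershed splitting.  Blobs combine by maximum so touching nuclei keep
  distinct peaks.
* **The screen.** Per plate: negative-control (DMSO) wells at the aligned
  baseline κ = 2, a positive control (Y-27632 at 10 µmol/L) with kappa
  multiplier 0.22 — chosen once so the measured alignment fraction drops by
  ≈ 50 %, the benchmark effect size the assay is designed to detect — and
  test compounds whose planted effects are multiplicative κ (and optionally
  nuclei-count or hole-fraction) factors.  Per-well seeds derive from the
  master seed by a counter-based scheme, so screens are bit-reproducible and
  wells are independent.  The configured fiber count (300) refers to the
  512 × 512 px default FOV and is scaled by `min(shape)/512` so fiber areal
  density is resolution-independent.

With these defaults the *measured* alignment fraction rises monotonically
from ≈ 0.27 (κ = 0, the structure-tensor floor just above the analytic
41/180) to ≈ 0.8–0.86 at the κ = 2 baseline, with well-to-well CVs of a few
percent — the regime in which the real assay was credentialed.  Note the
mapping from κ to measured fraction is *not* the raw von Mises orientation
fraction: pixel weights concentrate along straight, coherent fibers, which
sharpens the measured histogram relative to the sampled angles.

**What the simulator does not emulate** — and hence what passing tests do
not show about real data: curved or branching fibers, optical PSF and
depth-dependent blur, bleed-through between channels, uneven illumination,
cell bodies occluding matrix, and biological well-to-well variability beyond
orientation sampling noise.  Recovery results on simulated screens
demonstrate that the *pipeline* is correct and sensitive at the stated
effect sizes, not that any particular biological screen will behave this
way.

## Problem sizes used in tests and the acceptance script

The test suite runs the hit-recovery experiment at 25 compounds (5 planted
with κ multipliers 0.05–0.15, i.e. ≥ 50 % alignment-fraction reductions,
always at least as strong as the reference effect that defines the hit
threshold), 3 replicate plates, 256 × 256 px FOVs and 10 master seeds;
credentialing properties use 128 × 96 px images and 20 seeds.  These sizes
were chosen to make the stochastic properties sharp (≥ 3 SD margins) while
keeping a full run on a single CPU in minutes; the acceptance script runs
the same experiment at 3 master seeds.  All thresholds asserted by tests are
the screen's published rules or closed-form values, never quantities tuned
to the generator.

## Known limitations

* The structure-tensor settings (σ = 1/2 px) are one reasonable choice for
  ~1–3 px-wide fibers; thicker fibers in downsampled images may need larger
  windows (both are config keys).
* The alignment statistic saturates near 1 for near-perfectly parallel
  fields, compressing strong-effect differences (real matrices rarely reach
  this regime).
* Otsu thresholding assumes a bimodal nuclei-intensity histogram; extremely
  sparse or confluent fields may need the fixed-threshold override.
* The published screen's own raw-image tallies (exclusion counts, the > 75 %
  sufficient-image rate, per-condition Z values) require the original
  microscope data and are out of reach; the package tests the rules and
  identities they instantiate instead.
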