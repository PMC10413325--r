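---
title: "Aligning and analyzing line-scan MSI data with dynamic scan periods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aligning and analyzing line-scan MSI data with dynamic scan periods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msiline)
```

## Why line-scan MSI needs its own rasterization

Continuous-ionization MSI (DESI, nano-DESI) acquires an image as parallel
line scans: the stage moves under the probe at constant speed, the mass
spectrometer acquires as fast as it can, and each line is stored as its own
file. On Orbitrap instruments the automatic gain control (AGC) adapts the
ion injection time per scan to hold a target charge count. That is good for
spectral quality and dynamic range, but it makes the scan period — and
therefore the pixel width — different for every scan. Two consequences
follow: lines have different numbers of scans, and equal scan indices on
different lines correspond to different stage positions. A raster built by
stacking scans by index is therefore distorted, increasingly so toward line
ends where period differences accumulate.

The fix implemented here is a *virtual time axis*. For the selected scan
filter:

1. each line's matching scan times are re-referenced to that line's first
   matching scan, so every line starts at t = 0 (the absolute acquisition
   clock carries an arbitrary lead-in per line and is discarded);
2. the axis runs from 0 to `tmax`, the longest line-relative duration over
   all lines, extended to the first tick at or beyond `tmax` so no scan
   falls off the grid;
3. the grid spacing `dt` is the dataset-wide **median** inter-scan interval
   of the matching scans — a robust location of the typical duty cycle that
   single AGC outliers (e.g. one very slow scan over dense tissue) cannot
   shift;
4. each tick takes the value of the scan whose time is nearest
   (**closest-value interpolation**). When a tick is exactly equidistant
   between two scans, the earlier scan wins — an arbitrary but fixed
   convention that keeps rasterization deterministic.

Closest-value interpolation is chosen over linear or spline interpolation
deliberately: every non-fill pixel equals one *observed* intensity bit for
bit, so pixel values remain measured quantities that survive round trips
through exports, and detection (a pixel "contains" a peak) stays
well-defined for the nontargeted machinery. The cost is sub-pixel jitter at
sharp boundaries, discussed under limitations.

Ticks whose nearest scan is farther than one grid spacing away lie beyond a
short line's end. They are stored as 0 and flagged in a fill mask rather
than padded with the edge value: repeating the last scan would smear tissue
edges outward, and the mask lets every exporter and statistic distinguish
"not acquired" from "measured zero". Fill pixels are excluded from contrast
percentiles and from image-to-phantom comparisons, but they *count* inside
a drawn ROI (a user outlining a region owns all its pixels, so `n_pixels`
reflects drawn area).

Pixel geometry follows from acquisition parameters: width = `dt` × stage
speed, height = line step. The defaults (20 µm/s, 75 µm) describe a typical
pneumatically-assisted nano-DESI setting with ~1 s Orbitrap scans, giving
pixels about 20 µm wide and 75 µm tall; rendering and export honor that
ratio.

## Targeted extraction

Matching is symmetric in ppm: a centroid matches a target when
|(m_obs − m_t)/m_t|·10⁶ ≤ tol, and among matches the lowest |ppm| wins.
The ppm error is reported *signed* so systematic calibration offsets remain
visible. Exact ties (one centroid above, one below, identical |ppm|) are
resolved toward the higher intensity, then the lower m/z — in measured
double-precision data ties are essentially impossible, but a defined order
makes the operation a function. The per-spectrum implementation evaluates
all centroids × all targets as one difference matrix; this is a speed
contract only, and the test suite holds it equal to an exhaustive
per-pair search on randomized spectra.

The tolerance should sit well above the instrument's centroid jitter: for
Orbitrap-class data with ~1–2 ppm scan-to-scan jitter, a 5 ppm tolerance is
a 2.5–3σ gate that will drop an isolated clean peak every few hundred
scans, whereas 10 ppm (≥5σ) makes misses negligible without admitting
neighbors more than 10 ppm away. The quantification examples in this
package use 10 ppm for exactly that reason.

## Normalization and one-point quantification

TIC normalization divides each pixel by that spectrum's total ion current —
a nonspecific correction for overall ionization fluctuations. With an
internal standard doped into the solvent, the analyte can instead be
normalized to a co-ionized reference, and with the standard's concentration
`C_IS` and a response factor the image becomes quantitative:

$$ C = \frac{I_\mathrm{analyte}}{I_\mathrm{IS}} \cdot \frac{C_\mathrm{IS}}{RF},
\qquad RF = \frac{I_\mathrm{analyte}/C_\mathrm{analyte}}{I_\mathrm{IS}/C_\mathrm{IS}} $$

The direction of `RF` is a convention; it is stated here (and in
`?quant_params`) so users whose calibration defines the reciprocal can pass
`1/RF`. Division guards: pixels where the reference is zero or fill map to
0, never NaN or Inf, and the count of guarded pixels is reported — exports
stay numeric and a sudden rise in guarded pixels is a usable warning sign.
Quantification operates on raw intensities; the hot-pixel percentile clamp
is strictly a display operation.

## ROI analysis

A polygon ROI (programmatic stand-in for freehand drawing) is rasterized by
pixel-center inclusion under the even-odd rule, with centers at
(col + 0.5, row + 0.5) and boundary centers included. This is the simplest
rule that is exactly deterministic and matches what a user expects from a
drawn outline; identical vertices on an identical grid always give the
identical mask, which is what makes vertex-only ROI files reloadable.
Masks persist as human-readable JSON (name, grid shape, vertices,
run-length-encoded mask) so they can be audited or consumed by other
software; a mask is never silently rescaled onto a grid of another shape —
that is always an error.

## Nontargeted feature grouping

Centroid m/z values of one chemical species jitter between spectra, and
FTMS resolving power falls with increasing m/z, so fixed-width bins either
split features at high m/z or merge them at low m/z. Grouping is therefore
relative: pooled peaks are sorted by m/z and a group boundary is placed
wherever the gap to the previous peak exceeds the tolerance in ppm
(relative to the previous m/z) — one-dimensional single-linkage clustering.
The algorithm is deterministic, independent of input order, and can never
split a run of peaks all closer than the tolerance. Its known failure mode
is chaining: a dense run of peaks can accumulate a total spread beyond the
tolerance. Rather than pretending this cannot happen, each group reports
`spread_ppm` (maximum member deviation from the centroid) so users can
histogram it and tighten the tolerance if chains appear.

Group centroids are intensity-weighted means by default (robust to
low-intensity jitter; an unweighted mean is available). Detection frequency
is the fraction of ROI pixels containing at least one member peak; mean
intensity is summed member intensity over *detected* pixels, not all ROI
pixels, so the intensity filter and the frequency filter remain independent
axes. A peak detects a pixel whenever its intensity is positive — minimum
intensity floors belong in the screening criteria, not in pooling.

Two-ROI screening pools peaks from the union of both ROIs, groups once
(so a feature has one identity in both regions), and ranks by fold change
(mean_A + ε)/(mean_B + ε). The pseudocount ε = 1 count exists purely to
keep groups absent from one ROI finite; against real intensities of 10³–10⁷
counts it perturbs genuine ratios by well under a part per thousand. It is
configurable for data on other intensity scales.

## Display and export

The contrast limit is the nearest-rank percentile (rank ⌈p/100·n⌉ of the
sorted non-fill values) — exact and reproducible, unlike interpolated
percentiles that differ between software. Values above the limit are
clamped at render time only. Zero pixels stay in the percentile population:
excluding them would silently brighten sparse channels. CSV export writes
raw values at full precision (`%.17g`, lossless for doubles) with a fill
mask sidecar; PNG/TIFF export writes the rendered view, optionally as
16-bit grayscale.

## The synthetic-data generator

The generator exists so every claim in the test suite can be checked
against known truth. It emulates, per line: scan times accumulating
jittered periods (uniform multipliers on `[1−a, 1+a]`, the bounded,
assumption-light default; Gaussian optional) until the nominal line
duration ends; a random absolute lead-in per line (exercising the
line-relative re-referencing); per-scan sampling of each analyte's spatial
map at the stage position implied by the scan time; multiplicative
log-normal intensity noise; Gaussian centroid m/z jitter in ppm; a constant
solvent-doped internal standard; ubiquitous solvent background peaks; and
optionally an interlaced SIM filter every k-th scan. Output is
standards-compliant centroided mzML 1.1 (times declared in minutes, the
converter convention), byte-identical under a fixed seed.

Default conditions are fixed once and mirror a realistic
pneumatically-assisted nano-DESI acquisition: 20 µm/s stage speed, 75 µm
line step, 1.0 s nominal scan period, ±30% AGC jitter, 2% intensity noise,
1.5 ppm centroid jitter, and an internal standard emulating 0.5 µM PC 25:0
(at a synthetic stand-in m/z). Three presets cover the validation axes:

* **alignment** (30 × 60): a smooth two-dimensional sinusoidal field plus a
  moderate disc. Distortion removal is measured on structure the pixel grid
  can represent, because closest-value interpolation carries an
  *irreducible* sub-pixel sampling error at razor edges that no alignment
  can remove; measuring on smooth structure isolates the AGC distortion
  itself. Validation compares the aligned TIC image with the phantom
  evaluated at the achieved grid positions, over non-fill pixels (fill
  pixels are "not acquired" and would otherwise measure line-length spread,
  not distortion).
* **two-region** (30 × 60): one region-specific analyte at 10× the
  intensity of 20 ubiquitous analytes plus background — the screening
  scenario, where the planted feature must be the only group passing a
  frequency ∈ [0.1, 1], fold ≥ 2 screen.
* **gradient** (20 × 50): analyte concentration rising linearly 0.2→1.0 µM
  against a constant internal standard, painted so that quantification with
  RF = 1.5 and C_IS = 0.5 µM recovers the map.

What the generator does *not* emulate — and what passing tests therefore do
not show: resolution-dependent peak shapes and merging of near-isobars,
space-charge m/z shifts correlated with TIC, matrix-dependent ionization
suppression varying across tissue, detector saturation, and electronic
noise floors. Tests against these phantoms validate the *data handling*;
they cannot validate instrument physics.

## Numerical choices and degenerate inputs

* Grid size: the axis extends to the first tick ≥ `tmax` (so
  `n_ticks = ⌈tmax/dt⌉ + 1`, with a relative guard of 10⁻⁹ against float
  noise on exact multiples).
* Nearest-tick ties break toward the earlier scan / lower tick, in both
  mapping directions (tick→scan for images, scan→tick for peak pooling).
* A line lacking the selected filter, an empty path list, a degenerate
  (zero-area or empty-mask) polygon, a shape mismatch between image and
  mask, and non-positive tolerances or quantification parameters are all
  hard errors naming the offending object; an empty spectrum aligns to an
  all-fill row; a missing TIC attribute falls back to the intensity sum
  with a notice.
* File order: line index comes from the supplied path order;
  `sort_line_paths()` provides numeric-aware filename sorting because
  per-line files rarely embed an explicit row index.

## Validation problem sizes

The shipped suite validates on: 20 simulated lines × 30 scans × 50 peaks
for mzML round trips; the 30-line alignment phantom under ±30% jitter; 1000
randomized spectra/target-list cases against a brute-force extraction
oracle; 200 pools of up to 500 peaks against a transitive-closure grouping
oracle at five tolerances; 100 random polygon masks against first-principles
statistics; and the full two-region screening scenario. These sizes keep
the whole suite around a minute while giving the randomized oracles enough
trials to catch boundary mistakes; `scripts/acceptance.R` re-runs the same
program at any seed.

## Known limitations

* Single polygon per ROI (no holes); draw multiple ROIs for composite
  regions.
* No isotope deconvolution, adduct enumeration, or database annotation —
  feature groups are m/z clusters, nothing more.
* No statistical testing across ROIs; the screen is a filter, not a test.
* Profile-mode spectra are accepted with a warning but not centroided;
  centroid upstream.
* The median-spaced grid means pixel width is a dataset property; two
  datasets of the same tissue can have slightly different grids.
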