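Package: msiline
Title: Ion Images from Line-Scan Mass Spectrometry Imaging with Dynamic Scan Periods
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds distortion-free ion images from per-line centroided mzML
    files acquired with continuous-ionization mass spectrometry imaging
    sources (DESI, nano-DESI) under automatic gain control, where every scan
    has a slightly different duty cycle and therefore pixel width. Each line
    is interpolated onto a shared virtual time axis by closest-value
    interpolation, preserving observed intensities. Includes targeted feature
    extraction by ppm-tolerance difference matrices, TIC and internal-standard
    normalization with one-point quantification, polygon region-of-interest
    statistics, nontargeted ppm-tolerance feature grouping with two-region
    accumulation/depletion screening, percentile-clamped rendering and
    CSV/PNG/TIFF export, plus a ground-truthed synthetic dataset generator
    emulating AGC timing jitter.
License: MIT
Encoding: UTF-8
Imports:
    mzR,
    jsonlite,
    optparse,
    png,
    tiff,
    grDevices,
    tools,
    graphics,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
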