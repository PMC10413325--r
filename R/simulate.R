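#' AGC timing model for the synthetic-data generator
#'
#' Automatic gain control adapts the ion injection time per scan, so the scan
#' period — and hence the pixel width — varies from scan to scan. The
#' generator draws each scan period as `base_period_s` times a multiplier
#' from a bounded uniform distribution `[1 - jitter, 1 + jitter]` (default)
#' or a Gaussian with that standard deviation.
#'
#' @param base_period_s Nominal scan period in seconds.
#' @param jitter Half-width (uniform) or SD (gaussian) of the period
#'   multiplier; must leave all periods positive.
#' @param distribution `"uniform"` (default) or `"gaussian"`.
#' @return An `AGCModel` list.
#' @export
agc_model <- function(base_period_s = 1.0, jitter = 0.3,
                      distribution = c("uniform", "gaussian")) {
  distribution <- match.arg(distribution)
  stopifnot(base_period_s > 0, jitter >= 0, jitter < 1)
  structure(list(base_period_s = base_period_s, jitter = jitter,
                 distribution = distribution),
            class = "AGCModel")
}

# Multiplicative period factors, one per draw
.agc_multipliers <- function(agc, n) {
  if (agc$jitter == 0) return(rep(1, n))
  if (agc$distribution == "uniform") {
    stats::runif(n, 1 - agc$jitter, 1 + agc$jitter)
  } else {
    pmax(stats::rnorm(n, 1, agc$jitter), 0.05)
  }
}

#' Spatial phantom for synthetic line-scan MSI data
#'
#' Defines a ground-truthed sample: named analytes with simple spatial maps
#' (disc, rectangle, half-plane, uniform, linear x-gradient) on an
#' `n_lines x n_cols` nominal pixel grid, a constant internal standard doped
#' into the solvent, ubiquitous solvent background peaks, multiplicative
#' intensity noise, and centroid m/z jitter in ppm. Spatial coordinates are
#' in nominal pixel units: a scan at line-relative time t samples
#' `x = t / base_period` and line r samples `y = r`.
#'
#' @param n_lines,n_cols Nominal image size (lines x pixels per line).
#' @param analytes List of analytes, each a list with `mz`, `annotation`,
#'   `intensity` (peak intensity scale) and `shape` (a list with `type` in
#'   `"uniform"`, `"disc"` (`center`, `radius`), `"rect"` (`x0,x1,y0,y1`,
#'   half-open), `"half_plane"` (`x0`), `"gradient_x"` (`from`, `to`)).
#' @param internal_standard List with `mz`, `intensity`, `annotation` for the
#'   solvent-doped internal standard (constant everywhere), or `NULL`.
#' @param background Data.frame with `mz`, `intensity` of ubiquitous solvent
#'   peaks (may have zero rows).
#' @param noise_cv Coefficient of variation of the multiplicative
#'   (log-normal) intensity noise applied per peak per scan.
#' @param mz_jitter_ppm SD of the Gaussian per-centroid m/z jitter, in ppm.
#' @return A `PhantomSpec` list.
#' @export
phantom_spec <- function(n_lines, n_cols, analytes = list(),
                         internal_standard = list(
                           mz = 664.4917, intensity = 1e4,
                           annotation = "PC 25:0 (internal standard, synthetic)"),
                         background = data.frame(mz = numeric(0),
                                                 intensity = numeric(0)),
                         noise_cv = 0.02, mz_jitter_ppm = 1.5) {
  stopifnot(n_lines >= 1, n_cols >= 2, noise_cv >= 0, mz_jitter_ppm >= 0)
  structure(list(n_lines = as.integer(n_lines), n_cols = as.integer(n_cols),
                 analytes = analytes, internal_standard = internal_standard,
                 background = background, noise_cv = noise_cv,
                 mz_jitter_ppm = mz_jitter_ppm),
            class = "PhantomSpec")
}

# Map multiplier of a shape at pixel coordinates (x, y); vectorized over x
.shape_value <- function(shape, x, y, n_cols) {
  switch(shape$type,
    uniform = rep(1, length(x)),
    disc = as.numeric((x - shape$center[1])^2 + (y - shape$center[2])^2
                      <= shape$radius^2),
    rect = as.numeric(x >= shape$x0 & x < shape$x1 &
                      y >= shape$y0 & y < shape$y1),
    half_plane = as.numeric(x >= shape$x0),
    sinusoid = 0.25 * (1 + sin(2 * pi * x / shape$wavelength_x)) *
               (1 + sin(2 * pi * y / shape$wavelength_y)),
    gradient_x = shape$from + (shape$to - shape$from) * x / (n_cols - 1),
    stop("unknown shape type '", shape$type, "'", call. = FALSE)
  )
}

#' Noise-free phantom raster (ground truth)
#'
#' Evaluates the phantom's expected intensity on a pixel grid — the reference
#' against which aligned images are validated. By default the nominal grid
#' (`n_cols` columns at the nominal period) is used; pass `dt_s` and
#' `n_ticks` to evaluate at the achieved virtual-time-axis positions
#' `x = j * dt_s / base_period_s`.
#'
#' @param phantom A `PhantomSpec`.
#' @param channel `"TIC"` (all analytes + IS + background), `"IS"`, or the
#'   index of an analyte.
#' @param n_ticks,dt_s,base_period_s Optional achieved-grid description.
#' @return Numeric matrix `[n_lines x n_ticks]`.
#' @export
phantom_raster <- function(phantom, channel = "TIC", n_ticks = NULL,
                           dt_s = NULL, base_period_s = 1.0) {
  stopifnot(inherits(phantom, "PhantomSpec"))
  if (is.null(n_ticks)) n_ticks <- phantom$n_cols
  if (is.null(dt_s)) dt_s <- base_period_s
  x <- (seq_len(n_ticks) - 1) * dt_s / base_period_s
  out <- matrix(0, phantom$n_lines, n_ticks)
  add_analyte <- function(a) {
    t(vapply(seq_len(phantom$n_lines) - 1L, function(r) {
      a$intensity * .shape_value(a$shape, x, r, phantom$n_cols)
    }, numeric(n_ticks)))
  }
  if (identical(channel, "TIC")) {
    for (a in phantom$analytes) out <- out + add_analyte(a)
    if (!is.null(phantom$internal_standard)) {
      out <- out + phantom$internal_standard$intensity
    }
    if (nrow(phantom$background) > 0L) {
      out <- out + sum(phantom$background$intensity)
    }
  } else if (identical(channel, "IS")) {
    out[] <- phantom$internal_standard$intensity
  } else {
    out <- add_analyte(phantom$analytes[[channel]])
  }
  out
}

#' Generate a ground-truthed synthetic line-scan dataset
#'
#' Emulates a continuous-ionization MSI acquisition with AGC: per line, scan
#' times accumulate jittered periods until the nominal line duration
#' (`n_cols * base_period_s`) ends, each line starting at a small random
#' absolute time offset (lead-in before the probe reaches the sample origin).
#' Each scan samples every phantom channel at the stage position implied by
#' its time, applies multiplicative intensity noise, jitters each centroid
#' m/z by the stated ppm SD, and is written to one centroided mzML file per
#' line. Optionally every `interlace$every`-th scan is replaced by a SIM scan
#' with a different filter string containing only the internal-standard peak.
#'
#' The same seed reproduces the dataset byte-for-byte.
#'
#' @param phantom A [phantom_spec()].
#' @param agc An [agc_model()].
#' @param geometry An [acquisition_geometry()].
#' @param out_dir Output directory (created if needed).
#' @param seed Integer RNG seed.
#' @param interlace `NULL`, or a list with `every` (integer >= 2) and
#'   optionally `scan_filter`.
#' @param scan_filter Filter string written on the (full) scans.
#' @param write_truth Also write ground-truth rasters (CSV) and a manifest
#'   (JSON) recording the seed and parameters.
#' @return List with `paths` (mzML files in line order), `manifest_path`,
#'   `phantom`, `agc`, `geometry`.
#' @export
generate_dataset <- function(phantom, agc, geometry = acquisition_geometry(),
                             out_dir, seed = 1L, interlace = NULL,
                             scan_filter = "FTMS + p ESI Full ms [100.00-1000.00]",
                             write_truth = TRUE) {
  stopifnot(inherits(phantom, "PhantomSpec"), inherits(agc, "AGCModel"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(as.integer(seed))
  sim_filter <- if (!is.null(interlace)) {
    if (is.null(interlace$scan_filter))
      sprintf("FTMS + p ESI SIM ms [%.2f-%.2f]",
              phantom$internal_standard$mz - 0.5,
              phantom$internal_standard$mz + 0.5)
    else interlace$scan_filter
  } else NULL

  duration <- phantom$n_cols * agc$base_period_s
  paths <- character(phantom$n_lines)
  for (r in seq_len(phantom$n_lines) - 1L) {
    t0 <- stats::runif(1, 0, 2)
    times <- 0
    t <- 0
    repeat {
      t <- t + agc$base_period_s * .agc_multipliers(agc, 1L)
      if (t >= duration) break
      times <- c(times, t)
    }
    spectra <- vector("list", length(times))
    for (k in seq_along(times)) {
      is_sim <- !is.null(interlace) && (k %% interlace$every == 0L)
      x <- times[k] / agc$base_period_s
      mzs <- numeric(0); ints <- numeric(0)
      noisy <- function(v) v * exp(stats::rnorm(length(v), 0, phantom$noise_cv))
      if (!is_sim) {
        for (a in phantom$analytes) {
          v <- a$intensity * .shape_value(a$shape, x, r, phantom$n_cols)
          if (v > 0) { mzs <- c(mzs, a$mz); ints <- c(ints, noisy(v)) }
        }
        if (nrow(phantom$background) > 0L) {
          mzs <- c(mzs, phantom$background$mz)
          ints <- c(ints, noisy(phantom$background$intensity))
        }
      }
      if (!is.null(phantom$internal_standard)) {
        mzs <- c(mzs, phantom$internal_standard$mz)
        ints <- c(ints, noisy(phantom$internal_standard$intensity))
      }
      if (phantom$mz_jitter_ppm > 0 && length(mzs) > 0L) {
        mzs <- mzs * (1 + stats::rnorm(length(mzs), 0,
                                       phantom$mz_jitter_ppm) / 1e6)
      }
      o <- order(mzs)
      spectra[[k]] <- list(mz = mzs[o], intensity = ints[o],
                           time_s = t0 + times[k],
                           scan_filter = if (is_sim) sim_filter else scan_filter,
                           tic = sum(ints))
    }
    line <- structure(list(source_id = sprintf("line_%03d.mzML", r),
                           line_index = r, spectra = spectra),
                      class = "LineScan")
    paths[r + 1L] <- file.path(out_dir, sprintf("line_%03d.mzML", r))
    write_mzml(line, paths[r + 1L])
  }

  manifest_path <- NULL
  if (write_truth) {
    truth_tic <- phantom_raster(phantom, "TIC", base_period_s = agc$base_period_s)
    utils::write.table(truth_tic, file.path(out_dir, "truth_tic.csv"),
                       sep = ",", row.names = FALSE, col.names = FALSE)
    for (i in seq_along(phantom$analytes)) {
      utils::write.table(
        phantom_raster(phantom, i, base_period_s = agc$base_period_s),
        file.path(out_dir, sprintf("truth_analyte_%02d.csv", i)),
        sep = ",", row.names = FALSE, col.names = FALSE)
    }
    manifest_path <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(
      list(seed = as.integer(seed),
           n_lines = phantom$n_lines, n_cols = phantom$n_cols,
           base_period_s = agc$base_period_s, jitter = agc$jitter,
           distribution = agc$distribution,
           noise_cv = phantom$noise_cv, mz_jitter_ppm = phantom$mz_jitter_ppm,
           speed_um_per_s = geometry$speed_um_per_s,
           line_step_um = geometry$line_step_um,
           scan_filter = scan_filter, sim_filter = sim_filter,
           analyte_mz = vapply(phantom$analytes, `[[`, numeric(1), "mz"),
           files = basename(paths)),
      manifest_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(paths = paths, manifest_path = manifest_path, phantom = phantom,
       agc = agc, geometry = geometry)
}

#' Write a line scan as a centroided mzML file
#'
#' Emits minimal standards-compliant mzML 1.1: per spectrum the centroided
#' m/z and intensity arrays (64-bit little-endian floats, base64, no
#' compression), the scan start time (declared in minutes, the converter
#' convention), the verbatim scan-filter string, and the total ion current.
#' A spectrum whose `tic` is `NA` is written without the TIC attribute
#' (readers then fall back to the intensity sum). Output is deterministic:
#' the same `LineScan` always produces identical bytes.
#'
#' @param line A `LineScan`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mzml <- function(line, path) {
  stopifnot(inherits(line, "LineScan"))
  enc <- function(x) {
    # base64_enc hard-wraps long output; mzML <binary> must be one run
    gsub("\n", "", jsonlite::base64_enc(writeBin(as.double(x), raw(),
                                                 size = 8L, endian = "little")),
         fixed = TRUE)
  }
  spec_xml <- function(i, sp) {
    mzb <- enc(sp$mz)
    inb <- enc(sp$intensity)
    ticp <- if (!is.null(sp$tic) && !is.na(sp$tic)) {
      sprintf('      <cvParam cvRef="MS" accession="MS:1000285" name="total ion current" value="%.17g"/>\n',
              sp$tic)
    } else ""
    paste0(
      sprintf('    <spectrum index="%d" id="scan=%d" defaultArrayLength="%d">\n',
              i - 1L, i, length(sp$mz)),
      '      <cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="1"/>\n',
      '      <cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum" value=""/>\n',
      '      <cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum" value=""/>\n',
      ticp,
      '      <scanList count="1">\n',
      '        <cvParam cvRef="MS" accession="MS:1000795" name="no combination" value=""/>\n',
      '        <scan>\n',
      sprintf('          <cvParam cvRef="MS" accession="MS:1000016" name="scan start time" value="%.17g" unitCvRef="UO" unitAccession="UO:0000031" unitName="minute"/>\n',
              sp$time_s / 60),
      sprintf('          <cvParam cvRef="MS" accession="MS:1000512" name="filter string" value="%s"/>\n',
              sp$scan_filter),
      '        </scan>\n',
      '      </scanList>\n',
      '      <binaryDataArrayList count="2">\n',
      sprintf('        <binaryDataArray encodedLength="%d">\n', nchar(mzb)),
      '          <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>\n',
      '          <cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>\n',
      '          <cvParam cvRef="MS" accession="MS:1000514" name="m/z array" value="" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>\n',
      sprintf('          <binary>%s</binary>\n', mzb),
      '        </binaryDataArray>\n',
      sprintf('        <binaryDataArray encodedLength="%d">\n', nchar(inb)),
      '          <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>\n',
      '          <cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>\n',
      '          <cvParam cvRef="MS" accession="MS:1000515" name="intensity array" value="" unitCvRef="MS" unitAccession="MS:1000131" unitName="number of detector counts"/>\n',
      sprintf('          <binary>%s</binary>\n', inb),
      '        </binaryDataArray>\n',
      '      </binaryDataArrayList>\n',
      '    </spectrum>\n')
  }
  header <- paste0(
    '<?xml version="1.0" encoding="utf-8"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">\n',
    '  <cvList count="2">\n',
    '    <cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>\n',
    '    <cv id="UO" fullName="Unit Ontology" URI="http://obo.cvs.sourceforge.net/obo/obo/ontology/phenotype/unit.obo"/>\n',
    '  </cvList>\n',
    '  <fileDescription><fileContent>\n',
    '    <cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum" value=""/>\n',
    '    <cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum" value=""/>\n',
    '  </fileContent></fileDescription>\n',
    '  <softwareList count="1"><software id="sw" version="0.1"><cvParam cvRef="MS" accession="MS:1000799" name="custom unreleased software tool" value="msiline simulator"/></software></softwareList>\n',
    '  <instrumentConfigurationList count="1"><instrumentConfiguration id="IC1">\n',
    '    <cvParam cvRef="MS" accession="MS:1000031" name="instrument model" value=""/>\n',
    '  </instrumentConfiguration></instrumentConfigurationList>\n',
    '  <dataProcessingList count="1"><dataProcessing id="dp1"><processingMethod order="1" softwareRef="sw">\n',
    '    <cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML" value=""/>\n',
    '  </processingMethod></dataProcessing></dataProcessingList>\n',
    '  <run id="run1" defaultInstrumentConfigurationRef="IC1">\n',
    sprintf('    <spectrumList count="%d" defaultDataProcessingRef="dp1">\n',
            length(line$spectra)))
  body <- vapply(seq_along(line$spectra),
                 function(i) spec_xml(i, line$spectra[[i]]), character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, body, '    </spectrumList>\n  </run>\n</mzML>'),
             con, sep = "")
  writeLines("", con)
  invisible(path)
}

#' Built-in phantom: two regions for ROI screening
#'
#' One region-specific analyte painted only inside a rectangular region A at
#' 10x the intensity of 20 ubiquitous analytes, plus solvent background peaks
#' and the internal standard — the scenario for validating two-ROI
#' accumulation screening (region-specific feature recovered, ubiquitous
#' features rejected). Polygon vertices for region A and a disjoint region B
#' are attached as `roi_a_vertices` / `roi_b_vertices`.
#'
#' @param n_lines,n_cols Image size.
#' @param planted_intensity Intensity of the region-specific analyte.
#' @param ubiquitous_intensity Intensity of each ubiquitous analyte.
#' @param ... Passed to [phantom_spec()] (e.g. `noise_cv`, `mz_jitter_ppm`).
#' @return A `PhantomSpec` with ROI vertex attributes.
#' @export
phantom_two_region <- function(n_lines = 30, n_cols = 60,
                               planted_intensity = 5e4,
                               ubiquitous_intensity = 5e3, ...) {
  planted <- list(mz = 400.2500, annotation = "planted region-specific",
                  intensity = planted_intensity,
                  shape = list(type = "rect", x0 = 8, x1 = 26,
                               y0 = 5, y1 = 25))
  ubiq <- lapply(seq_len(20), function(i) {
    list(mz = 400 + 20 * i + 0.30, annotation = sprintf("ubiquitous %02d", i),
         intensity = ubiquitous_intensity, shape = list(type = "uniform"))
  })
  ph <- phantom_spec(n_lines, n_cols, analytes = c(list(planted), ubiq),
                     background = data.frame(
                       mz = c(150.10, 200.15, 250.20, 301.10, 350.05),
                       intensity = c(2e3, 1.5e3, 3e3, 1e3, 2.5e3)),
                     ...)
  ph$roi_a_vertices <- cbind(c(8, 26, 26, 8), c(5, 5, 25, 25))
  ph$roi_b_vertices <- cbind(c(32, 56, 56, 32), c(5, 5, 25, 25))
  ph
}

#' Built-in phantom: smooth structure for alignment validation
#'
#' Tissue-like spatial structure at scales the pixel grid can represent: a
#' smooth two-dimensional sinusoidal intensity field plus a moderate-contrast
#' disc, over solvent background and the internal standard. Closest-value
#' interpolation carries an irreducible sub-pixel sampling error at razor
#' edges that no alignment can remove, so distortion removal is measured on a
#' phantom whose variation is dominated by resolvable structure; the raster
#' correlation then isolates the AGC timing distortion itself.
#'
#' @param n_lines,n_cols Image size.
#' @param ... Passed to [phantom_spec()].
#' @return A `PhantomSpec`.
#' @export
phantom_alignment <- function(n_lines = 30, n_cols = 60, ...) {
  phantom_spec(
    n_lines, n_cols,
    analytes = list(
      list(mz = 500.3000, annotation = "smooth field",
           intensity = 5e4,
           shape = list(type = "sinusoid", wavelength_x = 15,
                        wavelength_y = 10)),
      list(mz = 600.3500, annotation = "disc",
           intensity = 2e4,
           shape = list(type = "disc", center = c(42, 15), radius = 8))),
    background = data.frame(mz = c(150.10, 250.20), intensity = c(2e3, 3e3)),
    ...)
}

#' Built-in phantom: concentration gradient for quantification
#'
#' One analyte whose true concentration rises linearly along the scan axis
#' from `c_from` to `c_to` (same unit as `is_concentration`), with a constant
#' internal-standard channel. Analyte intensities are painted as
#' `C * RF * I_IS / C_IS`, so one-point quantification with the stated
#' parameters recovers the concentration map. The true concentration raster
#' is `phantom_raster(ph, 1, ...) / ph$conc_to_intensity`.
#'
#' @param n_lines,n_cols Image size.
#' @param c_from,c_to Concentration at the first/last nominal column.
#' @param is_concentration Internal-standard concentration (e.g. uM).
#' @param response_factor Analyte/IS response factor.
#' @param is_intensity Internal-standard peak intensity.
#' @param ... Passed to [phantom_spec()].
#' @return A `PhantomSpec` with fields `quant` (a [quant_params()]) and
#'   `conc_to_intensity` (intensity counts per concentration unit).
#' @export
phantom_gradient <- function(n_lines = 20, n_cols = 50,
                             c_from = 0.2, c_to = 1.0,
                             is_concentration = 0.5, response_factor = 1.5,
                             is_intensity = 1e4, ...) {
  k <- response_factor * is_intensity / is_concentration
  analyte <- list(mz = 760.5851, annotation = "gradient analyte",
                  intensity = k,
                  shape = list(type = "gradient_x", from = c_from, to = c_to))
  ph <- phantom_spec(n_lines, n_cols, analytes = list(analyte),
                     internal_standard = list(
                       mz = 664.4917, intensity = is_intensity,
                       annotation = "PC 25:0 (internal standard, synthetic)"),
                     background = data.frame(mz = c(150.10, 250.20),
                                             intensity = c(2e3, 3e3)),
                     ...)
  ph$quant <- quant_params(is_concentration, response_factor)
  ph$conc_to_intensity <- k
  ph
}
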