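#' Read one line scan from a centroided mzML file
#'
#' Continuous-ionization MSI instruments store each raster line as a separate
#' mass-spectrometry file. This reads one such mzML file (via \pkg{mzR}) and
#' returns the per-scan fields downstream processing needs: the centroided
#' mass spectrum, the scan start time, the instrument scan-filter string, and
#' the total ion current (TIC).
#'
#' Scan start times are returned in seconds relative to the file start,
#' whatever unit the file declares (mzML files converted from vendor raw data
#' usually declare minutes). When a spectrum carries no TIC attribute the sum
#' of its centroid intensities is used instead. Profile-mode spectra trigger a
#' warning but are processed as-is; centroid upstream (e.g. with msconvert)
#' for meaningful results.
#'
#' @param path Path to a centroided mzML file holding one raster line.
#' @param line_index Zero-based row position of this line in the image.
#' @return A `LineScan`: list with `source_id` (file name), `line_index`, and
#'   `spectra`, a time-ordered list of spectra. Each spectrum is a list with
#'   `mz` (ascending), `intensity`, `time_s`, `scan_filter`, `tic`.
#' @seealso [load_dataset()] to read a whole image, [write_mzml()] for the
#'   matching writer used by the synthetic-data generator.
#' @export
read_line_scan <- function(path, line_index = 0L) {
  if (!file.exists(path)) {
    stop("mzML file not found: ", path, call. = FALSE)
  }
  fh <- tryCatch(
    mzR::openMSfile(path),
    error = function(e) {
      stop("failed to parse mzML file '", path, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  on.exit(mzR::close(fh), add = TRUE)

  hdr <- mzR::header(fh)
  if (nrow(hdr) == 0L) {
    stop("mzML file '", path, "' contains no spectra", call. = FALSE)
  }
  if (any(!hdr$centroided, na.rm = TRUE)) {
    warning("file '", basename(path),
            "' contains profile-mode spectra; they are used as-is, ",
            "but centroiding upstream is recommended", call. = FALSE)
  }

  pk <- mzR::peaks(fh)
  if (is.matrix(pk)) pk <- list(pk)

  spectra <- vector("list", nrow(hdr))
  n_tic_fallback <- 0L
  for (i in seq_len(nrow(hdr))) {
    m <- pk[[i]]
    mz <- as.numeric(m[, 1L])
    inten <- as.numeric(m[, 2L])
    if (is.unsorted(mz)) {         # mzML requires ascending m/z; be tolerant
      o <- order(mz)
      mz <- mz[o]
      inten <- inten[o]
    }
    tic <- hdr$totIonCurrent[i]
    if (is.na(tic) || tic <= 0) {
      tic <- sum(inten)
      n_tic_fallback <- n_tic_fallback + 1L
    }
    fs <- hdr$filterString[i]
    spectra[[i]] <- list(
      mz = mz,
      intensity = inten,
      time_s = hdr$retentionTime[i],   # mzR reports seconds
      scan_filter = if (is.na(fs)) "" else fs,
      tic = tic
    )
  }
  if (n_tic_fallback > 0L) {
    message("read_line_scan: ", n_tic_fallback, " spectrum/spectra in '",
            basename(path), "' had no TIC attribute; using intensity sums")
  }

  times <- vapply(spectra, `[[`, numeric(1), "time_s")
  spectra <- spectra[order(times)]

  structure(
    list(source_id = basename(path),
         line_index = as.integer(line_index),
         spectra = spectra),
    class = "LineScan"
  )
}

#' Acquisition geometry of a line-scan image
#'
#' @param speed_um_per_s Stage speed along the scan axis, in micrometres per
#'   second. Together with the scan period this sets the pixel width.
#' @param line_step_um Step between adjacent lines along the perpendicular
#'   axis, in micrometres; this is the pixel height.
#' @return An `AcquisitionGeometry` list.
#' @export
acquisition_geometry <- function(speed_um_per_s = 20, line_step_um = 75) {
  if (!is.numeric(speed_um_per_s) || length(speed_um_per_s) != 1L ||
      !is.finite(speed_um_per_s) || speed_um_per_s <= 0) {
    stop("speed_um_per_s must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(line_step_um) || length(line_step_um) != 1L ||
      !is.finite(line_step_um) || line_step_um <= 0) {
    stop("line_step_um must be a single positive number", call. = FALSE)
  }
  structure(list(speed_um_per_s = speed_um_per_s, line_step_um = line_step_um),
            class = "AcquisitionGeometry")
}

#' Load a full line-scan imaging dataset
#'
#' Reads an ordered set of per-line mzML files into an `ImagingDataset`.
#' `line_index` is assigned from position in `paths` (row 0 first): file
#' names rarely embed an explicit row index, so acquisition order is the
#' caller's responsibility — [sort_line_paths()] provides a numeric-aware
#' filename sort for the common `line_1, line_2, ..., line_10` layout.
#'
#' @param paths Character vector of mzML paths in acquisition (row) order.
#' @param geometry An [acquisition_geometry()].
#' @return An `ImagingDataset`: list with `lines` (list of `LineScan`),
#'   `geometry`, and `filters` (distinct scan-filter strings present).
#' @export
load_dataset <- function(paths, geometry = acquisition_geometry()) {
  if (length(paths) == 0L) {
    stop("no mzML files given", call. = FALSE)
  }
  stopifnot(inherits(geometry, "AcquisitionGeometry"))
  lines <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    lines[[i]] <- read_line_scan(paths[[i]], line_index = i - 1L)
  }
  filters <- unique(unlist(lapply(lines, function(ln) {
    vapply(ln$spectra, `[[`, character(1), "scan_filter")
  })))
  structure(list(lines = lines, geometry = geometry, filters = filters),
            class = "ImagingDataset")
}

#' Sort mzML paths in natural (numeric-aware) filename order
#'
#' Plain lexicographic sorting puts `line_10` before `line_2`; this sorts
#' embedded integers numerically so that file order matches row order for the
#' usual one-file-per-line naming schemes.
#'
#' @param paths Character vector of file paths.
#' @return The paths reordered.
#' @export
sort_line_paths <- function(paths) {
  base <- basename(paths)
  # split each name into alternating non-digit / digit runs and build a
  # sortable key: digits compare numerically, text case-insensitively
  pieces <- regmatches(base, gregexpr("[0-9]+|[^0-9]+", base))
  maxlen <- max(vapply(pieces, length, integer(1)))
  keys <- lapply(seq_len(maxlen), function(k) {
    part <- vapply(pieces, function(p) if (k <= length(p)) p[k] else "",
                   character(1))
    num <- suppressWarnings(as.numeric(part))
    if (all(!is.na(num) | part == "")) {
      num[is.na(num)] <- -Inf
      num
    } else {
      tolower(part)
    }
  })
  paths[do.call(order, keys)]
}

#' Tabulate the scan filters present in a dataset
#'
#' Multiscan experiments interlace several scan types (full MS, SIM windows,
#' MSn) distinguished by their instrument filter strings; images are built per
#' filter. This lists each distinct filter with its scan count.
#'
#' @param dataset An `ImagingDataset`.
#' @return A data.frame with columns `scan_filter` and `n_scans`; counts sum
#'   to the total number of spectra.
#' @export
list_scan_filters <- function(dataset) {
  stopifnot(inherits(dataset, "ImagingDataset"))
  all_filters <- unlist(lapply(dataset$lines, function(ln) {
    vapply(ln$spectra, `[[`, character(1), "scan_filter")
  }))
  tab <- table(all_filters)
  # report in first-appearance order, as an operator would list them
  first <- unique(all_filters)
  data.frame(scan_filter = first,
             n_scans = as.integer(tab[first]),
             row.names = NULL,
             stringsAsFactors = FALSE)
}

#' @export
print.LineScan <- function(x, ...) {
  times <- vapply(x$spectra, `[[`, numeric(1), "time_s")
  cat("LineScan '", x$source_id, "' (row ", x$line_index, "): ",
      length(x$spectra), " scans, ",
      sprintf("%.2f-%.2f s", min(times), max(times)), "\n", sep = "")
  invisible(x)
}

#' @export
print.ImagingDataset <- function(x, ...) {
  n_scans <- sum(vapply(x$lines, function(ln) length(ln$spectra), integer(1)))
  cat("ImagingDataset: ", length(x$lines), " lines, ", n_scans, " scans, ",
      length(x$filters), " scan filter(s)\n", sep = "")
  cat("  geometry: ", x$geometry$speed_um_per_s, " um/s along line, ",
      x$geometry$line_step_um, " um line step\n", sep = "")
  for (f in x$filters) cat("  filter: ", f, "\n", sep = "")
  invisible(x)
}

# Matching scans of one line for a filter, with line-relative times.
# Returns list(times, spectra) or errors naming the line.
.matching_scans <- function(line, scan_filter) {
  fs <- vapply(line$spectra, `[[`, character(1), "scan_filter")
  keep <- which(fs == scan_filter)
  if (length(keep) == 0L) {
    stop("scan filter '", scan_filter, "' absent from line ", line$line_index,
         " ('", line$source_id, "')", call. = FALSE)
  }
  sp <- line$spectra[keep]
  times <- vapply(sp, `[[`, numeric(1), "time_s")
  list(times = times - times[1L], spectra = sp)
}
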