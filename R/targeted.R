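#' Load a targeted analyte list
#'
#' The analyte list is a two-column table: monoisotopic m/z in the first
#' column and an optional annotation in the second. Comma- and tab-separated
#' files are both accepted; a header row (non-numeric first cell) is skipped
#' with a notice. Entries without an annotation get the placeholder
#' `"feature not annotated"`.
#'
#' @param path Path to the CSV/TSV analyte list.
#' @return A data.frame with columns `mz` (numeric) and `annotation`.
#' @export
load_target_list <- function(path) {
  if (!file.exists(path)) stop("target list not found: ", path, call. = FALSE)
  raw <- readLines(path, warn = FALSE)
  raw <- raw[nzchar(trimws(raw))]
  if (length(raw) == 0L) stop("target list '", path, "' is empty", call. = FALSE)
  sep <- if (grepl("\t", raw[1L])) "\t" else ","
  cells <- strsplit(raw, sep, fixed = TRUE)

  first_val <- suppressWarnings(as.numeric(trimws(vapply(cells, `[[`, character(1), 1L))))
  start <- 1L
  if (is.na(first_val[1L])) {
    message("load_target_list: skipping header row in '", basename(path), "'")
    start <- 2L
    if (length(raw) < 2L) {
      stop("target list '", path, "' has a header but no data rows", call. = FALSE)
    }
  }
  rows <- seq.int(start, length(raw))
  mz <- first_val[rows]
  bad <- which(is.na(mz) | mz <= 0)
  if (length(bad) > 0L) {
    stop("target list '", path, "': non-numeric or non-positive m/z in row ",
         rows[bad[1L]], call. = FALSE)
  }
  annotation <- vapply(cells[rows], function(cc) {
    a <- if (length(cc) >= 2L) trimws(cc[[2L]]) else ""
    if (nzchar(a)) a else "feature not annotated"
  }, character(1))
  data.frame(mz = mz, annotation = annotation, stringsAsFactors = FALSE)
}

#' Extract listed m/z features from one spectrum
#'
#' For each target, a difference matrix between every spectrum centroid and
#' every target m/z is evaluated in one vectorized step; centroids within the
#' ppm threshold compete and the one with the lowest absolute ppm error wins.
#' The ppm error is `(observed - target) / target * 1e6`, reported signed;
#' selection uses its absolute value. If two centroids tie exactly (one above
#' and one below the target) the more intense wins, then the lower m/z.
#'
#' @param spectrum A spectrum list (`mz`, `intensity`, ...).
#' @param targets Data.frame with columns `mz` and optionally `annotation`
#'   (see [load_target_list()]), or a numeric vector of target m/z.
#' @param tol_ppm Positive ppm tolerance.
#' @return A data.frame with one row per target: `target_mz`, `annotation`,
#'   `observed_mz`, `intensity`, `ppm_error`. Targets with no centroid inside
#'   the tolerance have `NA` observed m/z and ppm error and intensity 0.
#' @export
extract_from_spectrum <- function(spectrum, targets, tol_ppm) {
  targets <- .as_target_df(targets)
  if (!is.numeric(tol_ppm) || length(tol_ppm) != 1L || !is.finite(tol_ppm) ||
      tol_ppm <= 0) {
    stop("tol_ppm must be a single positive number", call. = FALSE)
  }
  n_t <- nrow(targets)
  out <- data.frame(target_mz = targets$mz,
                    annotation = targets$annotation,
                    observed_mz = NA_real_,
                    intensity = 0,
                    ppm_error = NA_real_,
                    stringsAsFactors = FALSE)
  mz <- spectrum$mz
  if (length(mz) == 0L || n_t == 0L) return(out)

  # difference matrix, centroids x targets, in ppm of the target
  ppm <- outer(mz, targets$mz, function(o, t) (o - t) / t * 1e6)
  inten <- spectrum$intensity
  for (j in seq_len(n_t)) {
    e <- ppm[, j]
    ok <- which(abs(e) <= tol_ppm)
    if (length(ok) == 0L) next
    best <- ok[abs(e[ok]) == min(abs(e[ok]))]
    if (length(best) > 1L) {                   # exact |ppm| tie
      best <- best[inten[best] == max(inten[best])]
      best <- best[which.min(mz[best])]
    }
    out$observed_mz[j] <- mz[best]
    out$intensity[j] <- inten[best]
    out$ppm_error[j] <- e[best]
  }
  out
}

.as_target_df <- function(targets) {
  if (is.numeric(targets)) {
    targets <- data.frame(mz = as.numeric(targets),
                          annotation = "feature not annotated",
                          stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(targets), "mz" %in% names(targets))
  if (is.null(targets$annotation)) targets$annotation <- "feature not annotated"
  if (any(!is.finite(targets$mz) | targets$mz <= 0)) {
    stop("target m/z values must be positive and finite", call. = FALSE)
  }
  targets
}

#' Build one ion image per targeted analyte
#'
#' Runs [extract_from_spectrum()] over every matching scan and aligns each
#' target's matched intensities onto the shared virtual time axis. Pixels
#' where the target is not detected (no centroid within tolerance) are 0.
#'
#' @inheritParams build_image
#' @param targets Target table or numeric vector (see [extract_from_spectrum()]).
#' @param tol_ppm Positive ppm matching tolerance.
#' @return A list of `IonImage`, one per target, in target order; channels
#'   are labelled `"m/z <target> (<annotation>)"`.
#' @export
build_target_images <- function(dataset, scan_filter, targets, tol_ppm,
                                grid = NULL) {
  stopifnot(inherits(dataset, "ImagingDataset"))
  targets <- .as_target_df(targets)
  if (is.null(grid)) grid <- build_time_grid(dataset, scan_filter)
  n_lines <- length(dataset$lines)
  n_t <- nrow(targets)

  imgs <- lapply(seq_len(n_t), function(j) {
    new_ion_image(matrix(0, n_lines, grid$n_ticks),
                  matrix(TRUE, n_lines, grid$n_ticks),
                  pixel_width_um = grid$dt_s * dataset$geometry$speed_um_per_s,
                  pixel_height_um = dataset$geometry$line_step_um,
                  channel = sprintf("m/z %.4f (%s)", targets$mz[j],
                                    targets$annotation[j]))
  })
  for (i in seq_len(n_lines)) {
    ms <- .matching_scans(dataset$lines[[i]], scan_filter)
    # intensities: scans x targets (0 where no hit)
    hits <- vapply(ms$spectra, function(sp) {
      extract_from_spectrum(sp, targets, tol_ppm)$intensity
    }, numeric(n_t))
    hits <- matrix(hits, nrow = n_t)           # vapply drops dim for n_t == 1
    for (j in seq_len(n_t)) {
      row <- align_line(ms$times, hits[j, ], grid)
      imgs[[j]]$values[i, ] <- row$values
      imgs[[j]]$fill_mask[i, ] <- row$fill
    }
  }
  imgs
}
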