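#' Build the virtual time axis for a scan filter
#'
#' Under automatic gain control each scan's duty cycle differs, so lines have
#' different numbers of scans at irregular times and a naive scan-index raster
#' is distorted. The fix is a shared virtual time axis: each line is
#' re-referenced to its first matching scan (line-relative t = 0), the axis
#' runs from 0 to the longest line-relative duration over all lines, and its
#' spacing is the dataset-wide median inter-scan interval for the selected
#' filter (robust to AGC outliers). The axis extends to the first tick at or
#' beyond the longest duration, so every acquired scan falls inside the grid.
#'
#' @param dataset An `ImagingDataset`.
#' @param scan_filter Scan-filter string to grid; must occur in every line.
#' @return A `TimeGrid`: list with `t0_s` (0), `tmax_s`, `dt_s`, `n_ticks`,
#'   and `ticks`.
#' @export
build_time_grid <- function(dataset, scan_filter) {
  stopifnot(inherits(dataset, "ImagingDataset"))
  if (!scan_filter %in% dataset$filters) {
    stop("scan filter '", scan_filter, "' not present in dataset; available: ",
         paste(sQuote(dataset$filters), collapse = ", "), call. = FALSE)
  }
  rel <- lapply(dataset$lines, function(ln) .matching_scans(ln, scan_filter)$times)
  tmax <- max(vapply(rel, function(t) t[length(t)], numeric(1)))
  intervals <- unlist(lapply(rel, diff))
  if (length(intervals) == 0L) {
    stop("cannot determine grid spacing: every line has a single matching scan",
         call. = FALSE)
  }
  dt <- stats::median(intervals)
  if (dt <= 0) {
    stop("non-positive median inter-scan interval; scan times are degenerate",
         call. = FALSE)
  }
  # smallest n with (n-1)*dt >= tmax, tolerating float noise on exact multiples
  ratio <- tmax / dt
  n <- floor(ratio + 1e-9) + 1L
  if ((n - 1L) * dt < tmax - 1e-9 * dt) n <- n + 1L
  structure(
    list(t0_s = 0, tmax_s = tmax, dt_s = dt, n_ticks = as.integer(n),
         ticks = (seq_len(n) - 1) * dt),
    class = "TimeGrid"
  )
}

#' @export
print.TimeGrid <- function(x, ...) {
  cat(sprintf("TimeGrid: %d ticks, dt = %.4g s, span 0-%.4g s (tmax %.4g s)\n",
              x$n_ticks, x$dt_s, x$ticks[x$n_ticks], x$tmax_s))
  invisible(x)
}

# Index of the nearest tick to each time (0-based), ties toward the lower
# tick; the same mapping rule in both directions (scan->tick and tick->scan).
.nearest_tick <- function(times, grid) {
  r <- times / grid$dt_s
  j <- floor(r)
  frac <- r - j
  j <- ifelse(frac > 0.5 + 1e-12, j + 1, j)
  as.integer(pmin(pmax(j, 0), grid$n_ticks - 1L))
}

#' Align one line's scans onto a time grid
#'
#' Closest-value interpolation: each grid tick takes the value of the matching
#' scan whose (line-relative) time is nearest. No averaging or blending —
#' every non-fill output equals one observed input value exactly, which keeps
#' pixel values interpretable as measured intensities. Ticks whose nearest
#' scan lies farther than one grid spacing away (beyond a short line's end)
#' are set to 0 and flagged as fill.
#'
#' When a tick is exactly equidistant between two scans the earlier scan wins.
#'
#' @param times Ascending line-relative scan times (seconds).
#' @param values Per-scan scalar values, same length as `times`.
#' @param grid A `TimeGrid`.
#' @return List with `values` (length `n_ticks`) and `fill` (logical).
#' @export
align_line <- function(times, values, grid) {
  stopifnot(inherits(grid, "TimeGrid"), length(times) == length(values))
  n <- grid$n_ticks
  if (length(times) == 0L) {
    return(list(values = numeric(n), fill = rep(TRUE, n)))
  }
  if (is.unsorted(times, strictly = FALSE)) {
    stop("scan times must be ascending", call. = FALSE)
  }
  ticks <- grid$ticks
  pos <- findInterval(ticks, times)            # index of last time <= tick
  left <- pmax(pos, 1L)
  right <- pmin(pos + 1L, length(times))
  dl <- abs(ticks - times[left])
  dr <- abs(times[right] - ticks)
  use_left <- dl <= dr                         # tie -> earlier scan
  idx <- ifelse(use_left, left, right)
  dist <- pmin(dl, dr)
  fill <- dist > grid$dt_s * (1 + 1e-9)
  out <- values[idx]
  out[fill] <- 0
  list(values = out, fill = fill)
}

#' Build an ion image for a scan filter
#'
#' Applies [align_line()] to every line of the dataset, taking one scalar per
#' scan (by default the TIC) and producing a rectangular `[n_lines x n_ticks]`
#' pixel matrix on the shared virtual time axis. Pixel width is
#' `dt_s * speed`; pixel height is the line step.
#'
#' @param dataset An `ImagingDataset`.
#' @param scan_filter Scan filter selecting the spectra to rasterize.
#' @param per_scan_value Function mapping one spectrum (list with `mz`,
#'   `intensity`, `time_s`, `scan_filter`, `tic`) to one number. Default: TIC.
#' @param channel Channel label stored on the image; default `"TIC"`.
#' @param grid Optional precomputed `TimeGrid` (built if `NULL`).
#' @return An `IonImage`.
#' @export
build_image <- function(dataset, scan_filter,
                        per_scan_value = function(sp) sp$tic,
                        channel = "TIC", grid = NULL) {
  stopifnot(inherits(dataset, "ImagingDataset"))
  if (is.null(grid)) grid <- build_time_grid(dataset, scan_filter)
  n_lines <- length(dataset$lines)
  values <- matrix(0, nrow = n_lines, ncol = grid$n_ticks)
  fill <- matrix(TRUE, nrow = n_lines, ncol = grid$n_ticks)
  for (i in seq_len(n_lines)) {
    ms <- .matching_scans(dataset$lines[[i]], scan_filter)
    v <- vapply(ms$spectra, per_scan_value, numeric(1))
    row <- align_line(ms$times, v, grid)
    values[i, ] <- row$values
    fill[i, ] <- row$fill
  }
  new_ion_image(values, fill,
                pixel_width_um = grid$dt_s * dataset$geometry$speed_um_per_s,
                pixel_height_um = dataset$geometry$line_step_um,
                channel = channel)
}

#' Construct an IonImage
#'
#' The raster container shared by the whole package: a `[lines x ticks]`
#' value matrix (row 0 = first acquired line, column 0 = line start), a fill
#' mask flagging pixels beyond a line's acquired duration (stored as 0 but
#' distinguishable from true zeros), pixel geometry in micrometres, and a
#' channel label.
#'
#' @param values Numeric matrix of pixel values.
#' @param fill_mask Logical matrix, same shape; `TRUE` marks fill pixels.
#' @param pixel_width_um,pixel_height_um Pixel size along/across lines (um).
#' @param channel Free-text channel description (target m/z, "TIC", ratio...).
#' @return An `IonImage`.
#' @export
new_ion_image <- function(values, fill_mask = NULL,
                          pixel_width_um = 1, pixel_height_um = 1,
                          channel = "") {
  values <- as.matrix(values)
  if (is.null(fill_mask)) {
    fill_mask <- matrix(FALSE, nrow = nrow(values), ncol = ncol(values))
  }
  fill_mask <- as.matrix(fill_mask)
  stopifnot(identical(dim(values), dim(fill_mask)), is.logical(fill_mask))
  if (any(!is.finite(values[!fill_mask]))) {
    stop("non-finite pixel values outside the fill mask", call. = FALSE)
  }
  structure(
    list(values = values, fill_mask = fill_mask,
         pixel_width_um = pixel_width_um, pixel_height_um = pixel_height_um,
         channel = channel),
    class = "IonImage"
  )
}

#' @export
dim.IonImage <- function(x) dim(x$values)

#' @export
print.IonImage <- function(x, ...) {
  nf <- !x$fill_mask
  cat(sprintf(
    "IonImage '%s': %d lines x %d pixels (%.3g x %.3g um), %d fill px\n",
    x$channel, nrow(x$values), ncol(x$values),
    x$pixel_width_um, x$pixel_height_um, sum(x$fill_mask)))
  if (any(nf)) {
    cat(sprintf("  value range (non-fill): %.6g to %.6g\n",
                min(x$values[nf]), max(x$values[nf])))
  }
  invisible(x)
}

#' Naive scan-index rasterization (for distortion comparison)
#'
#' Stacks each line's matching scans by index, ignoring scan times — the
#' rasterization one would get by treating all pixels as equal width. Rows
#' shorter than the longest line are padded with fill. Provided so users can
#' see the AGC distortion that the virtual-time-axis alignment removes.
#'
#' @inheritParams build_image
#' @return An `IonImage` of dimension `[n_lines x max scans per line]`.
#' @export
build_image_naive <- function(dataset, scan_filter,
                              per_scan_value = function(sp) sp$tic,
                              channel = "TIC (unaligned)") {
  stopifnot(inherits(dataset, "ImagingDataset"))
  per_line <- lapply(dataset$lines, function(ln) {
    ms <- .matching_scans(ln, scan_filter)
    vapply(ms$spectra, per_scan_value, numeric(1))
  })
  n_cols <- max(vapply(per_line, length, integer(1)))
  n_lines <- length(per_line)
  values <- matrix(0, n_lines, n_cols)
  fill <- matrix(TRUE, n_lines, n_cols)
  for (i in seq_len(n_lines)) {
    v <- per_line[[i]]
    values[i, seq_along(v)] <- v
    fill[i, seq_along(v)] <- FALSE
  }
  # nominal pixel width from the median interval, as in build_time_grid
  grid <- build_time_grid(dataset, scan_filter)
  new_ion_image(values, fill,
                pixel_width_um = grid$dt_s * dataset$geometry$speed_um_per_s,
                pixel_height_um = dataset$geometry$line_step_um,
                channel = channel)
}
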