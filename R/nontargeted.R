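#' Pool every detected centroid from ROI pixels
#'
#' Collects all centroids of all matching scans whose aligned pixel falls
#' inside the ROI. A scan maps to the grid tick nearest its line-relative
#' time — the same nearest-time rule the image alignment uses — so pooled
#' peaks carry the `(line_index, tick_index)` pixel they would contribute to.
#' Zero-intensity centroids are dropped; detection floors belong to the
#' screening criteria, not to pooling.
#'
#' @inheritParams build_image
#' @param roi An `ROIMask` congruent with the filter's grid.
#' @return Data.frame of pooled peaks: `mz`, `intensity`, `line_index`,
#'   `tick_index`, `pixel_id` (`line_index * n_ticks + tick_index`).
#' @export
collect_peaks <- function(dataset, scan_filter, roi, grid = NULL) {
  stopifnot(inherits(dataset, "ImagingDataset"), inherits(roi, "ROIMask"))
  if (is.null(grid)) grid <- build_time_grid(dataset, scan_filter)
  if (!identical(dim(roi$mask), c(length(dataset$lines), grid$n_ticks))) {
    stop("ROI mask shape ", paste(dim(roi$mask), collapse = "x"),
         " does not match the ", length(dataset$lines), "x", grid$n_ticks,
         " grid for this scan filter", call. = FALSE)
  }
  acc <- vector("list", length(dataset$lines))
  for (i in seq_along(dataset$lines)) {
    ms <- .matching_scans(dataset$lines[[i]], scan_filter)
    ticks <- .nearest_tick(ms$times, grid)
    in_roi <- roi$mask[cbind(i, ticks + 1L)]
    if (!any(in_roi)) next
    keep <- which(in_roi)
    parts <- lapply(keep, function(k) {
      sp <- ms$spectra[[k]]
      pos <- sp$intensity > 0
      if (!any(pos)) return(NULL)
      data.frame(mz = sp$mz[pos], intensity = sp$intensity[pos],
                 line_index = i - 1L, tick_index = ticks[k])
    })
    acc[[i]] <- do.call(rbind, parts)
  }
  out <- do.call(rbind, acc)
  if (is.null(out)) {
    out <- data.frame(mz = numeric(0), intensity = numeric(0),
                      line_index = integer(0), tick_index = integer(0))
  }
  out$pixel_id <- out$line_index * grid$n_ticks + out$tick_index
  out
}

#' Group pooled centroids into ppm-tolerance feature groups
#'
#' Centroid m/z values of the same chemical species jitter slightly between
#' spectra, and because FTMS resolution varies with m/z, fixed-width bins
#' either split real features or merge distinct ones. Grouping is therefore
#' relative: peaks are sorted by m/z and a new group starts whenever the gap
#' to the previous peak exceeds `tol_ppm` (relative to the previous m/z) —
#' single-linkage clustering in one dimension. This is deterministic,
#' order-independent, and never splits a run of peaks closer than the
#' tolerance; the price is that a chain of close peaks can make a group's
#' total spread exceed the tolerance, so `spread_ppm` is reported per group
#' for quality control (its distribution is worth histogramming).
#'
#' @param peaks Data.frame from [collect_peaks()] (columns `mz`, `intensity`,
#'   `pixel_id`; extra columns are carried along).
#' @param tol_ppm Positive grouping tolerance in ppm.
#' @param weighted Use the intensity-weighted mean as the group centroid
#'   (default); `FALSE` for the unweighted mean.
#' @return A `FeatureGroups` object: list with `groups` (data.frame `group`,
#'   `centroid_mz`, `spread_ppm`, `n_members`, sorted by centroid m/z) and
#'   `peaks` (the input with a `group` column).
#' @export
group_features <- function(peaks, tol_ppm, weighted = TRUE) {
  if (!is.numeric(tol_ppm) || length(tol_ppm) != 1L || tol_ppm <= 0) {
    stop("tol_ppm must be a single positive number", call. = FALSE)
  }
  if (nrow(peaks) == 0L) {
    return(structure(list(
      groups = data.frame(group = integer(0), centroid_mz = numeric(0),
                          spread_ppm = numeric(0), n_members = integer(0)),
      peaks = cbind(peaks, group = integer(0)), tol_ppm = tol_ppm),
      class = "FeatureGroups"))
  }
  o <- order(peaks$mz)
  mz <- peaks$mz[o]
  gap_ppm <- diff(mz) / mz[-length(mz)] * 1e6
  grp_sorted <- cumsum(c(1L, as.integer(gap_ppm > tol_ppm)))
  grp <- integer(nrow(peaks))
  grp[o] <- grp_sorted

  inten <- peaks$intensity
  centroid <- vapply(split(seq_len(nrow(peaks)), grp), function(idx) {
    if (weighted) stats::weighted.mean(peaks$mz[idx], inten[idx])
    else mean(peaks$mz[idx])
  }, numeric(1))
  spread <- vapply(seq_along(centroid), function(g) {
    idx <- which(grp == g)
    max(abs(peaks$mz[idx] - centroid[g])) / centroid[g] * 1e6
  }, numeric(1))
  n_members <- as.integer(table(grp))

  peaks$group <- grp
  structure(list(
    groups = data.frame(group = seq_along(centroid), centroid_mz = centroid,
                        spread_ppm = spread, n_members = n_members),
    peaks = peaks, tol_ppm = tol_ppm),
    class = "FeatureGroups")
}

#' @export
print.FeatureGroups <- function(x, ...) {
  cat(sprintf("FeatureGroups: %d groups from %d peaks (tol %.3g ppm)\n",
              nrow(x$groups), nrow(x$peaks), x$tol_ppm))
  if (nrow(x$groups) > 0L) {
    cat(sprintf("  spread_ppm: median %.3g, max %.3g\n",
                stats::median(x$groups$spread_ppm), max(x$groups$spread_ppm)))
  }
  invisible(x)
}

#' Per-ROI aggregates of feature groups
#'
#' For each group: detection frequency = fraction of ROI pixels containing at
#' least one member peak; mean intensity = summed member intensity divided by
#' the number of detected pixels (a pixel holding two members contributes
#' their sum once). The mean is over detected pixels, not all ROI pixels, so
#' intensity filtering stays independent of frequency filtering.
#'
#' @param groups A `FeatureGroups` object.
#' @param roi The `ROIMask` to aggregate over.
#' @return Data.frame with one row per group: `group`, `centroid_mz`,
#'   `mean_intensity`, `det_freq`.
#' @export
group_stats <- function(groups, roi) {
  stopifnot(inherits(groups, "FeatureGroups"), inherits(roi, "ROIMask"))
  n_roi <- sum(roi$mask)
  nt <- ncol(roi$mask)
  pk <- groups$peaks
  in_roi <- roi$mask[cbind(pk$line_index + 1L, pk$tick_index + 1L)]
  out <- data.frame(group = groups$groups$group,
                    centroid_mz = groups$groups$centroid_mz,
                    mean_intensity = 0, det_freq = 0)
  if (nrow(pk) == 0L || !any(in_roi)) return(out)
  sub <- pk[in_roi, , drop = FALSE]
  for (g in out$group) {
    m <- sub[sub$group == g, , drop = FALSE]
    if (nrow(m) == 0L) next
    per_pixel <- tapply(m$intensity, m$pixel_id, sum)
    out$det_freq[g] <- length(per_pixel) / n_roi
    out$mean_intensity[g] <- sum(m$intensity) / length(per_pixel)
  }
  out
}

#' Screening criteria for two-ROI feature comparison
#'
#' @param intensity_range `c(min, max)` on the ROI-A mean intensity.
#' @param frequency_range `c(min, max)` on the ROI-A detection frequency
#'   (fractions in \[0, 1\]).
#' @param min_fold Minimum A/B fold change for a group to pass.
#' @return A `FilterCriteria` list.
#' @export
filter_criteria <- function(intensity_range = c(0, Inf),
                            frequency_range = c(0, 1),
                            min_fold = 1) {
  stopifnot(length(intensity_range) == 2L, intensity_range[1] <= intensity_range[2],
            length(frequency_range) == 2L, frequency_range[1] <= frequency_range[2],
            is.numeric(min_fold), min_fold > 0)
  structure(list(intensity_range = as.numeric(intensity_range),
                 frequency_range = as.numeric(frequency_range),
                 min_fold = as.numeric(min_fold)),
            class = "FilterCriteria")
}

#' Screen feature groups accumulated or depleted between two ROIs
#'
#' Pools peaks from the union of the two ROIs, groups them once, computes
#' per-ROI mean intensity and detection frequency, and ranks groups by fold
#' change `(mean_A + eps) / (mean_B + eps)`. The pseudocount `eps` (default 1
#' count) guards groups absent from one ROI without perturbing real intensity
#' ratios. With criteria supplied, only groups whose ROI-A intensity and
#' detection frequency fall inside the stated ranges and whose fold change
#' reaches `min_fold` are returned. Swapping the ROIs screens for depletion.
#' A typical background filter compares tissue against bare glass.
#'
#' @inheritParams collect_peaks
#' @param roi_a,roi_b `ROIMask`s congruent with the grid; fold change is A/B.
#' @param tol_ppm Grouping tolerance in ppm.
#' @param criteria Optional [filter_criteria()]; `NULL` returns all groups.
#' @param epsilon Fold-change pseudocount, in intensity counts.
#' @return Data.frame sorted by descending fold change: `centroid_mz`,
#'   `spread_ppm`, `n_members`, `mean_intensity_a`, `det_freq_a`,
#'   `mean_intensity_b`, `det_freq_b`, `fold_change`.
#' @export
compare_rois <- function(dataset, scan_filter, roi_a, roi_b, tol_ppm,
                         criteria = NULL, epsilon = 1, grid = NULL) {
  stopifnot(inherits(roi_a, "ROIMask"), inherits(roi_b, "ROIMask"))
  if (!is.null(criteria)) stopifnot(inherits(criteria, "FilterCriteria"))
  if (is.null(grid)) grid <- build_time_grid(dataset, scan_filter)
  union_roi <- structure(
    list(mask = roi_a$mask | roi_b$mask,
         vertices = roi_a$vertices,
         name = paste(roi_a$name, "|", roi_b$name)),
    class = "ROIMask")
  peaks <- collect_peaks(dataset, scan_filter, union_roi, grid = grid)
  groups <- group_features(peaks, tol_ppm)
  sa <- group_stats(groups, roi_a)
  sb <- group_stats(groups, roi_b)
  out <- data.frame(
    centroid_mz = groups$groups$centroid_mz,
    spread_ppm = groups$groups$spread_ppm,
    n_members = groups$groups$n_members,
    mean_intensity_a = sa$mean_intensity,
    det_freq_a = sa$det_freq,
    mean_intensity_b = sb$mean_intensity,
    det_freq_b = sb$det_freq)
  out$fold_change <- (out$mean_intensity_a + epsilon) /
                     (out$mean_intensity_b + epsilon)
  if (!is.null(criteria)) {
    keep <- out$mean_intensity_a >= criteria$intensity_range[1] &
      out$mean_intensity_a <= criteria$intensity_range[2] &
      out$det_freq_a >= criteria$frequency_range[1] &
      out$det_freq_a <= criteria$frequency_range[2] &
      out$fold_change >= criteria$min_fold
    out <- out[keep, , drop = FALSE]
  }
  out <- out[order(-out$fold_change, out$centroid_mz), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Ion image of one feature group
#'
#' Runs the targeted extraction over the whole grid with the group's centroid
#' m/z as the target, at the same ppm tolerance — identical to
#' [build_target_images()] with that m/z.
#'
#' @inheritParams build_image
#' @param centroid_mz The group's centroid m/z.
#' @param tol_ppm Extraction tolerance in ppm.
#' @return An `IonImage`.
#' @export
group_image <- function(dataset, scan_filter, centroid_mz, tol_ppm,
                        grid = NULL) {
  build_target_images(dataset, scan_filter, centroid_mz, tol_ppm,
                      grid = grid)[[1L]]
}
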