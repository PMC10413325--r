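# Even-odd (ray casting) point-in-polygon with boundary inclusion.
# px, py: vectors of query points; vx, vy: polygon vertices (open ring).
.points_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- logical(length(px))
  on_edge <- logical(length(px))
  eps <- 1e-9
  j <- n
  for (i in seq_len(n)) {
    xi <- vx[i]; yi <- vy[i]; xj <- vx[j]; yj <- vy[j]
    # boundary test: point within eps of segment (i, j)
    dx <- xj - xi; dy <- yj - yi
    len2 <- dx * dx + dy * dy
    if (len2 > 0) {
      t <- ((px - xi) * dx + (py - yi) * dy) / len2
      t <- pmin(pmax(t, 0), 1)
      d2 <- (px - (xi + t * dx))^2 + (py - (yi + t * dy))^2
      on_edge <- on_edge | d2 <= eps * eps
    } else {
      on_edge <- on_edge | ((px - xi)^2 + (py - yi)^2 <= eps * eps)
    }
    # crossing test (half-open in y to count shared vertices once)
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | on_edge
}

.polygon_area <- function(vx, vy) {
  n <- length(vx)
  j <- c(n, seq_len(n - 1L))
  abs(sum(vx * vy[j] - vx[j] * vy)) / 2
}

#' Rasterize a polygon into a region-of-interest mask
#'
#' Programmatic equivalent of drawing an ROI on an ion image: the polygon is
#' given as ordered vertices in pixel coordinates `(col, row)`, with the
#' origin at the image's top-left corner so that pixel `(r, c)` spans
#' `[c, c+1) x [r, r+1)`. A pixel belongs to the ROI iff its center
#' `(c + 0.5, r + 0.5)` lies inside the polygon by the even-odd rule; centers
#' exactly on the boundary are included. Rasterization is deterministic:
#' identical vertices and grid always give the identical mask.
#'
#' @param vertices Two-column matrix (or data.frame) of `(col, row)` polygon
#'   vertices, at least 3, in drawing order (ring closed implicitly).
#' @param grid_shape Integer vector `c(n_lines, n_ticks)` of the image grid,
#'   or an `IonImage` to take the shape from.
#' @param name ROI label.
#' @return An `ROIMask`: list with logical `mask`, `vertices`, `name`.
#' @export
mask_from_polygon <- function(vertices, grid_shape, name = "ROI") {
  vertices <- as.matrix(vertices)
  if (!is.numeric(vertices) || ncol(vertices) != 2L || nrow(vertices) < 3L) {
    stop("vertices must be a numeric matrix with >= 3 rows of (col, row)",
         call. = FALSE)
  }
  if (inherits(grid_shape, "IonImage")) grid_shape <- dim(grid_shape)
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 2L, all(grid_shape >= 1L))
  if (.polygon_area(vertices[, 1L], vertices[, 2L]) <= 0) {
    stop("degenerate polygon: zero area", call. = FALSE)
  }
  nr <- grid_shape[1L]; nc <- grid_shape[2L]
  cx <- rep(seq_len(nc) - 0.5, each = nr)     # column-major like R matrices
  cy <- rep(seq_len(nr) - 0.5, times = nc)
  inside <- .points_in_polygon(cx, cy, vertices[, 1L], vertices[, 2L])
  mask <- matrix(inside, nrow = nr, ncol = nc)
  if (!any(mask)) {
    stop("polygon covers no pixel center; ROI would be empty", call. = FALSE)
  }
  structure(list(mask = mask, vertices = vertices, name = name),
            class = "ROIMask")
}

#' @export
print.ROIMask <- function(x, ...) {
  cat(sprintf("ROIMask '%s': %d of %d pixels (%d vertices)\n",
              x$name, sum(x$mask), length(x$mask), nrow(x$vertices)))
  invisible(x)
}

#' Descriptive statistics of an ion image inside an ROI
#'
#' Fill pixels inside the ROI contribute their stored value 0 — they are part
#' of the drawn region, so `n_pixels` reflects the drawn area. The relative
#' standard deviation is `sd / mean * 100`; it is 0 for constant regions and
#' `NA` when the mean is 0 with nonzero spread.
#'
#' @param image An `IonImage`.
#' @param roi An `ROIMask` on the same grid.
#' @return One-row data.frame: `n_pixels`, `mean`, `median`, `sd`, `min`,
#'   `max`, `sum`, `rsd_pct`.
#' @export
roi_stats <- function(image, roi) {
  stopifnot(inherits(image, "IonImage"), inherits(roi, "ROIMask"))
  if (!identical(dim(image$values), dim(roi$mask))) {
    stop("ROI mask shape ", paste(dim(roi$mask), collapse = "x"),
         " does not match image grid ",
         paste(dim(image$values), collapse = "x"), call. = FALSE)
  }
  v <- image$values[roi$mask]
  s <- stats::sd(v)
  m <- mean(v)
  rsd <- if (is.na(s)) NA_real_
         else if (s == 0) 0
         else if (m == 0) NA_real_
         else s / m * 100
  data.frame(n_pixels = length(v), mean = m, median = stats::median(v),
             sd = s, min = min(v), max = max(v), sum = sum(v), rsd_pct = rsd)
}

#' Apply one ROI across several image channels
#'
#' @param images List of `IonImage`s on the same grid.
#' @param roi An `ROIMask`.
#' @return Data.frame with one row per channel (input order): `channel`
#'   followed by the [roi_stats()] columns.
#' @export
apply_roi_multi <- function(images, roi) {
  stopifnot(is.list(images), length(images) >= 1L)
  rows <- lapply(images, function(img) {
    cbind(data.frame(channel = img$channel, stringsAsFactors = FALSE),
          roi_stats(img, roi))
  })
  do.call(rbind, rows)
}

#' Save an ROI mask for later sessions
#'
#' Writes a human-inspectable JSON file carrying the ROI name, grid shape,
#' polygon vertices, and the boolean mask run-length encoded in row-major
#' order — readable in other software without this package. Optionally also
#' writes the raw 0/1 mask matrix as CSV.
#'
#' @param roi An `ROIMask`.
#' @param path Output JSON path.
#' @param csv_path Optional path for a 0/1 CSV raster of the mask.
#' @return `path`, invisibly.
#' @export
save_roi <- function(roi, path, csv_path = NULL) {
  stopifnot(inherits(roi, "ROIMask"))
  flat <- as.integer(t(roi$mask))              # row-major
  r <- rle(flat)
  obj <- list(
    name = roi$name,
    grid_shape = dim(roi$mask),
    vertices = unname(roi$vertices),
    mask_rle = list(lengths = r$lengths, values = r$values)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(csv_path)) {
    utils::write.table(roi$mask * 1L, csv_path, sep = ",",
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Reload a saved ROI mask
#'
#' The stored grid shape must match `grid_shape` when one is supplied; masks
#' are never silently rescaled onto a different grid. Files carrying only
#' vertices (no run-length mask) are re-rasterized with [mask_from_polygon()],
#' which is deterministic, so the mask is identical to the originally saved
#' one.
#'
#' @param path JSON file written by [save_roi()].
#' @param grid_shape Optional `c(n_lines, n_ticks)` (or `IonImage`) the mask
#'   must be congruent with.
#' @return An `ROIMask`.
#' @export
load_roi <- function(path, grid_shape = NULL) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  shape <- as.integer(obj$grid_shape)
  if (!is.null(grid_shape)) {
    if (inherits(grid_shape, "IonImage")) grid_shape <- dim(grid_shape)
    if (!identical(as.integer(grid_shape), shape)) {
      stop("ROI '", obj$name, "' was drawn on a ", paste(shape, collapse = "x"),
           " grid but the current grid is ",
           paste(as.integer(grid_shape), collapse = "x"),
           "; masks are not rescaled", call. = FALSE)
    }
  }
  vertices <- matrix(as.numeric(obj$vertices), ncol = 2L)
  if (!is.null(obj$mask_rle) && length(obj$mask_rle$lengths) > 0L) {
    flat <- inverse.rle(structure(list(
      lengths = as.integer(obj$mask_rle$lengths),
      values = as.integer(obj$mask_rle$values)), class = "rle"))
    mask <- matrix(as.logical(flat), nrow = shape[1L], ncol = shape[2L],
                   byrow = TRUE)
    structure(list(mask = mask, vertices = vertices, name = obj$name),
              class = "ROIMask")
  } else {
    mask_from_polygon(vertices, shape, name = obj$name)
  }
}
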