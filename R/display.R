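#' Hot-pixel contrast limit
#'
#' A single hot pixel can stretch a linear color scale until the tissue is
#' invisible. The automatic contrast tool caps the color scale at the
#' nearest-rank nth percentile of the non-fill pixel values: with `n` sorted
#' values, the limit is the value at rank `ceiling(p/100 * n)`. Values above
#' the limit are clamped at render time only — pixel data are never modified.
#' Fill pixels are excluded so that empty line tails do not depress contrast.
#'
#' @param image An `IonImage`.
#' @param percentile Percentile in (0, 100]; 100 means no clamping.
#' @return The scalar upper color limit.
#' @export
contrast_limit <- function(image, percentile = 99) {
  stopifnot(inherits(image, "IonImage"))
  if (!is.numeric(percentile) || length(percentile) != 1L ||
      percentile <= 0 || percentile > 100) {
    stop("percentile must be in (0, 100]", call. = FALSE)
  }
  v <- image$values[!image$fill_mask]
  if (length(v) == 0L) return(0)
  v <- sort(v)
  v[max(1L, ceiling(percentile / 100 * length(v)))]
}

#' Render an ion image to a color raster
#'
#' Maps pixel values through a perceptually uniform colormap with the color
#' scale capped at the [contrast_limit()]. In `"relative"` scale mode values
#' are divided by the limit to a \[0, 1\] relative-abundance scale (the
#' numbers shown to the user change, not the data). The physical pixel aspect
#' ratio `pixel_width_um : pixel_height_um` is carried along so plots and
#' exported pictures show true geometry.
#'
#' @param image An `IonImage`.
#' @param colormap Palette name passed to [grDevices::hcl.colors()] (e.g.
#'   `"viridis"`, `"inferno"`, `"mako"`); unknown names raise an error listing
#'   the available maps.
#' @param percentile Contrast percentile, see [contrast_limit()].
#' @param scale_mode `"absolute"` (default) or `"relative"`.
#' @param n_colors Number of colormap steps.
#' @return An `msi_render`: list with `rgb` (height x width x 3 array in
#'   \[0, 1\]), `norm` (clamped, normalized values), `limit`, `colormap`,
#'   `scale_mode`, and the pixel geometry.
#' @export
render_image <- function(image, colormap = "viridis", percentile = 99,
                         scale_mode = c("absolute", "relative"),
                         n_colors = 256L) {
  stopifnot(inherits(image, "IonImage"))
  scale_mode <- match.arg(scale_mode)
  pal_ok <- tolower(grDevices::hcl.pals())
  if (!tolower(colormap) %in% pal_ok) {
    stop("unknown colormap '", colormap, "'; available: ",
         paste(grDevices::hcl.pals(), collapse = ", "), call. = FALSE)
  }
  limit <- contrast_limit(image, percentile)
  norm <- if (limit > 0) pmin(image$values / limit, 1) else image$values * 0
  norm[norm < 0] <- 0
  cols <- grDevices::hcl.colors(n_colors, palette = colormap)
  idx <- pmin(floor(norm * (n_colors - 1L)) + 1L, n_colors)
  rgbm <- grDevices::col2rgb(cols[idx]) / 255
  nr <- nrow(image$values); nc <- ncol(image$values)
  arr <- array(0, dim = c(nr, nc, 3L))
  for (k in 1:3) arr[, , k] <- matrix(rgbm[k, ], nr, nc)
  structure(list(rgb = arr, norm = norm, limit = limit,
                 colormap = colormap, scale_mode = scale_mode,
                 pixel_width_um = image$pixel_width_um,
                 pixel_height_um = image$pixel_height_um,
                 channel = image$channel),
            class = "msi_render")
}

#' Plot an ion image
#'
#' Displays the rendered raster with the true physical aspect ratio (a pixel
#' 10 um wide and 75 um tall is drawn 7.5x taller than wide) unless
#' `aspect = FALSE`.
#'
#' @param x An `IonImage`.
#' @param colormap,percentile,scale_mode Passed to [render_image()].
#' @param aspect Keep the physical aspect ratio from the pixel geometry.
#' @param ... Ignored.
#' @return The `msi_render` used, invisibly.
#' @export
plot.IonImage <- function(x, colormap = "viridis", percentile = 99,
                          scale_mode = "absolute", aspect = TRUE, ...) {
  r <- render_image(x, colormap = colormap, percentile = percentile,
                    scale_mode = scale_mode)
  nr <- nrow(x$values); nc <- ncol(x$values)
  w <- nc * x$pixel_width_um
  h <- nr * x$pixel_height_um
  graphics::plot.new()
  graphics::plot.window(xlim = c(0, w), ylim = c(h, 0),
                        asp = if (aspect) 1 else NA)
  graphics::rasterImage(r$rgb, 0, h, w, 0, interpolate = FALSE)
  graphics::title(main = x$channel, xlab = "x (um)", ylab = "y (um)")
  graphics::axis(1); graphics::axis(2)
  invisible(r)
}

#' Export / import an ion image as a CSV matrix
#'
#' The CSV holds the raw (never clamped) pixel values, one row per line, at
#' full double precision so the round trip is exact. Fill pixels export as 0;
#' a sidecar `<path>.fillmask.csv` of 0/1 flags distinguishes them from true
#' zeros.
#'
#' @param image An `IonImage`.
#' @param path Output CSV path.
#' @param fill_sidecar Write the fill-mask sidecar (default `TRUE`).
#' @return `path`, invisibly.
#' @export
export_matrix <- function(image, path, fill_sidecar = TRUE) {
  stopifnot(inherits(image, "IonImage"))
  lines <- apply(image$values, 1L, function(r) {
    paste(sprintf("%.17g", r), collapse = ",")
  })
  writeLines(lines, path)
  if (fill_sidecar) {
    mlines <- apply(image$fill_mask * 1L, 1L, paste, collapse = ",")
    writeLines(mlines, paste0(path, ".fillmask.csv"))
  }
  invisible(path)
}

#' @rdname export_matrix
#' @return `import_matrix()`: an `IonImage` rebuilt from the CSV (and the
#'   fill-mask sidecar when present).
#' @param pixel_width_um,pixel_height_um,channel Metadata for the rebuilt
#'   image (CSV matrices do not carry geometry).
#' @export
import_matrix <- function(path, pixel_width_um = 1, pixel_height_um = 1,
                          channel = "") {
  values <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  dimnames(values) <- NULL
  sidecar <- paste0(path, ".fillmask.csv")
  fill <- if (file.exists(sidecar)) {
    m <- as.matrix(utils::read.table(sidecar, sep = ",", header = FALSE))
    dimnames(m) <- NULL
    m == 1
  } else NULL
  new_ion_image(values, fill, pixel_width_um, pixel_height_um, channel)
}

#' Export a rendered ion image as PNG or TIFF
#'
#' Writes the rendered (clamped, colormapped) view. `grayscale16 = TRUE`
#' writes the normalized values as 16-bit grayscale TIFF/PNG instead of RGB,
#' for downstream quantitative viewing. The physical aspect ratio is realized
#' by pixel replication along the shorter pixel dimension when `aspect` is
#' `TRUE` (an exported pixel block then has the true width : height ratio,
#' using integer replication factors).
#'
#' @param image An `IonImage` (rendered internally) or an `msi_render`.
#' @param path Output path; format from extension unless `format` is given.
#' @param format `"png"` or `"tiff"`.
#' @param grayscale16 Export 16-bit grayscale instead of RGB.
#' @param aspect Replicate pixels to the true aspect ratio.
#' @param ... Passed to [render_image()] when `image` is an `IonImage`.
#' @return `path`, invisibly.
#' @export
export_picture <- function(image, path, format = NULL, grayscale16 = FALSE,
                           aspect = FALSE, ...) {
  r <- if (inherits(image, "msi_render")) image else render_image(image, ...)
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("tif", "tiff")) "tiff" else "png"
  }
  format <- match.arg(format, c("png", "tiff"))
  img <- if (grayscale16) r$norm else r$rgb
  if (aspect) {
    ratio <- r$pixel_height_um / r$pixel_width_um
    ry <- max(1L, round(ratio))
    rx <- max(1L, round(1 / ratio))
    d <- dim(img)
    rep_rows <- rep(seq_len(d[1L]), each = ry)
    rep_cols <- rep(seq_len(d[2L]), each = rx)
    img <- if (length(d) == 3L) img[rep_rows, rep_cols, , drop = FALSE]
           else img[rep_rows, rep_cols, drop = FALSE]
  }
  if (format == "png") {
    png::writePNG(img, path)
  } else {
    tiff::writeTIFF(img, path, bits.per.sample = if (grayscale16) 16L else 8L)
  }
  invisible(path)
}
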