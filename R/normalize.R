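#' Pixel-wise normalization of an ion image
#'
#' Divides an analyte image by a reference image on the same grid — the TIC
#' channel for nonspecific normalization, or the internal-standard channel
#' for matrix-effect mitigation. Pixels where the reference is zero/negative,
#' or which are fill in either image, map to 0 (not NaN/Inf), keeping exports
#' numeric; the number of guarded pixels is reported via [message()].
#'
#' @param image Analyte `IonImage`.
#' @param reference Reference `IonImage` (e.g. TIC), same dimensions.
#' @return An `IonImage` of pixel-wise ratios, channel annotated as a ratio.
#' @export
normalize_image <- function(image, reference) {
  stopifnot(inherits(image, "IonImage"), inherits(reference, "IonImage"))
  if (!identical(dim(image$values), dim(reference$values))) {
    stop("image and reference dimensions differ: ",
         paste(dim(image$values), collapse = "x"), " vs ",
         paste(dim(reference$values), collapse = "x"), call. = FALSE)
  }
  fill <- image$fill_mask | reference$fill_mask
  guarded <- !fill & reference$values <= 0
  out <- image$values / reference$values
  out[fill | guarded] <- 0
  n_g <- sum(guarded)
  if (n_g > 0L) {
    message("normalize_image: ", n_g,
            " pixel(s) with non-positive reference set to 0")
  }
  new_ion_image(out, fill,
                pixel_width_um = image$pixel_width_um,
                pixel_height_um = image$pixel_height_um,
                channel = paste0(image$channel, " / ", reference$channel))
}

#' Internal-standard quantification parameters
#'
#' @param is_concentration Concentration of the internal standard in the
#'   solvent (any concentration unit, e.g. uM; the output inherits it).
#' @param response_factor Dimensionless relative response of the analyte vs
#'   the internal standard, `RF = (I_analyte / C_analyte) / (I_IS / C_IS)`.
#'   Users whose convention inverts this ratio should pass `1 / RF`.
#' @return A `QuantParams` list.
#' @export
quant_params <- function(is_concentration, response_factor = 1) {
  if (!is.numeric(is_concentration) || length(is_concentration) != 1L ||
      !is.finite(is_concentration) || is_concentration <= 0) {
    stop("is_concentration must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(response_factor) || length(response_factor) != 1L ||
      !is.finite(response_factor) || response_factor <= 0) {
    stop("response_factor must be a single positive number", call. = FALSE)
  }
  structure(list(is_concentration = is_concentration,
                 response_factor = response_factor),
            class = "QuantParams")
}

#' One-point quantification against an internal standard
#'
#' Continuous-ionization sources can dope an internal standard into the
#' solvent so that analyte and standard ionize simultaneously; with the
#' standard's known concentration and a relative response factor, each pixel
#' converts to a concentration:
#' \deqn{C = (I_{analyte} / I_{IS}) \times C_{IS} / RF}
#' Pixels with a non-positive internal-standard signal (or fill) map to 0.
#' Quantification operates on raw intensities; hot-pixel clamping is a
#' render-time operation only.
#'
#' @param analyte_image Analyte `IonImage`.
#' @param is_image Internal-standard `IonImage`, same grid.
#' @param params A [quant_params()].
#' @return An `IonImage` in concentration units (those of `is_concentration`).
#' @export
quantify <- function(analyte_image, is_image, params) {
  stopifnot(inherits(params, "QuantParams"))
  ratio <- normalize_image(analyte_image, is_image)
  out <- ratio
  out$values <- ratio$values * params$is_concentration / params$response_factor
  out$channel <- paste0(analyte_image$channel, " [conc]")
  out
}
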