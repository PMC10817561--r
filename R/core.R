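#' biodecomp: multispectral transmittance image decomposition
#'
#' Splits a stack of k transmittance images, acquired at k monochromatic
#' near-infrared wavelengths, into k per-tissue thickness images by solving
#' the per-pixel Beer-Lambert linear system with the inverse of a k x k
#' tissue attenuation coefficient matrix. See `vignette("biodecomp-methods")`
#' for the model, its assumptions and the numerical choices.
#'
#' @keywords internal
"_PACKAGE"

# Round half away from zero; base round() rounds half to even, which is the
# wrong convention for camera quantization here.
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Single-channel intensity image
#'
#' A grayscale camera frame: nonnegative counts, a bit depth, the saturation
#' count, and the illumination wavelength. Both the object image `I` and the
#' no-specimen reference image `I0` of the Beer-Lambert ratio `T = I / I0`
#' are represented this way.
#'
#' @param pixels Numeric matrix of nonnegative intensity counts (rows x cols).
#' @param bit_depth Integer, bits per sample; counts must not exceed
#'   `2^bit_depth - 1`.
#' @param wavelength_nm Positive wavelength in nanometres, or `NA` for images
#'   with no single illumination wavelength (e.g. rendered thickness maps).
#' @param saturation_level Count at or above which a pixel is considered
#'   saturated. Defaults to the full-scale count `2^bit_depth - 1`.
#' @return An object of class `intensity_image`.
#' @examples
#' img <- intensity_image(matrix(100, 2, 2), bit_depth = 8, wavelength_nm = 808)
#' @export
intensity_image <- function(pixels, bit_depth, wavelength_nm = NA_real_,
                            saturation_level = 2^bit_depth - 1) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix (single channel); got ",
         paste(class(pixels), collapse = "/"),
         if (length(dim(pixels)) == 3L)
           paste0(" with ", dim(pixels)[3L], " channels") else "")
  if (length(dim(pixels)) == 3L)
    stop("multi-channel image with ", dim(pixels)[3L],
         " channels; only single-channel images are supported")
  if (any(pixels < 0, na.rm = TRUE)) stop("negative pixel intensities")
  full_scale <- 2^bit_depth - 1
  if (any(pixels > full_scale, na.rm = TRUE))
    stop("pixel values exceed 2^bit_depth - 1 = ", full_scale)
  if (saturation_level > full_scale)
    stop("saturation_level exceeds 2^bit_depth - 1")
  if (!is.na(wavelength_nm) && wavelength_nm <= 0)
    stop("wavelength_nm must be positive")
  structure(list(pixels = pixels, bit_depth = as.integer(bit_depth),
                 saturation_level = saturation_level,
                 wavelength_nm = wavelength_nm),
            class = "intensity_image")
}

#' @export
print.intensity_image <- function(x, ...) {
  cat(sprintf("<intensity_image> %d x %d, %d-bit, wavelength %s nm, range [%g, %g]\n",
              nrow(x$pixels), ncol(x$pixels), x$bit_depth,
              format(x$wavelength_nm), min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.intensity_image <- function(x) dim(x$pixels)

#' Per-pixel transmittance of an object image against its reference
#'
#' Divides the object image by the no-specimen reference image taken at the
#' same wavelength, giving the transmittance `T(x, y) = I(x, y) / I0(x, y)`
#' in (0, 1]. Pixels where the reference is at or below the dark floor, or
#' where either image is saturated, carry no attenuation information and are
#' marked invalid. Values above 1 (possible with noise) are clamped to 1;
#' values at or below `eps` are clamped to `eps` so the downstream logarithm
#' stays finite; both clamps are counted in the diagnostics.
#'
#' @param object_img,reference_img [intensity_image()] pair of equal shape and
#'   wavelength; the reference is acquired without the specimen.
#' @param dark_floor_frac Reference pixels at or below this fraction of the
#'   saturation level are invalid (guards the division). Default 0.01.
#' @param eps Lower clamp for transmittance. Default 1e-6.
#' @return A list with `values` (matrix, `NA` where invalid), logical
#'   `valid_mask`, and clamp counters `n_clamped_high`, `n_clamped_low`.
#' @examples
#' obj <- intensity_image(matrix(50, 1, 1), 8, 808)
#' ref <- intensity_image(matrix(100, 1, 1), 8, 808)
#' transmittance(obj, ref)$values   # 0.5
#' @export
transmittance <- function(object_img, reference_img, dark_floor_frac = 0.01,
                          eps = 1e-6) {
  stopifnot(inherits(object_img, "intensity_image"),
            inherits(reference_img, "intensity_image"))
  if (!identical(dim(object_img$pixels), dim(reference_img$pixels)))
    stop("shape mismatch: object is ",
         paste(dim(object_img$pixels), collapse = "x"), ", reference is ",
         paste(dim(reference_img$pixels), collapse = "x"))
  if (!isTRUE(all.equal(object_img$wavelength_nm, reference_img$wavelength_nm)))
    stop("wavelength mismatch: object ", object_img$wavelength_nm,
         " nm vs reference ", reference_img$wavelength_nm, " nm")
  I <- object_img$pixels
  I0 <- reference_img$pixels
  dark_floor <- dark_floor_frac * reference_img$saturation_level
  valid <- (I0 > dark_floor) &
    (I0 < reference_img$saturation_level) &
    (I < object_img$saturation_level)
  vals <- I / I0
  n_hi <- sum(vals > 1 & valid, na.rm = TRUE)
  n_lo <- sum(vals <= eps & valid, na.rm = TRUE)
  vals[vals > 1] <- 1
  vals[vals <= eps] <- eps
  vals[!valid] <- NA_real_
  list(values = vals, valid_mask = valid,
       n_clamped_high = n_hi, n_clamped_low = n_lo)
}

#' Transmittance image stack over k wavelengths
#'
#' Converts k object/reference image pairs of one frame into a stack of
#' transmittance planes `T_lambda(x, y)`, one per wavelength, sharing a
#' common validity mask (a pixel is valid only if usable at every
#' wavelength).
#'
#' @param object_images,reference_images Lists of k [intensity_image()]s with
#'   matching wavelengths in matching order, all of one frame size.
#' @param dark_floor_frac,eps Passed to [transmittance()].
#' @return A `transmittance_stack`: `values` (rows x cols x k array, third
#'   dimension named by wavelength), `wavelengths_nm`, `valid_mask`, and
#'   total clamp counters.
#' @export
transmittance_stack <- function(object_images, reference_images,
                                dark_floor_frac = 0.01, eps = 1e-6) {
  k <- length(object_images)
  stopifnot(k >= 1, length(reference_images) == k)
  planes <- vector("list", k)
  wl <- numeric(k)
  for (i in seq_len(k)) {
    planes[[i]] <- transmittance(object_images[[i]], reference_images[[i]],
                                 dark_floor_frac = dark_floor_frac, eps = eps)
    wl[i] <- object_images[[i]]$wavelength_nm
  }
  shp <- dim(planes[[1]]$values)
  vals <- array(NA_real_, c(shp, k),
                dimnames = list(NULL, NULL, format(wl, trim = TRUE)))
  valid <- matrix(TRUE, shp[1], shp[2])
  for (i in seq_len(k)) {
    if (!identical(dim(planes[[i]]$values), shp))
      stop("all wavelengths must share one frame size")
    vals[, , i] <- planes[[i]]$values
    valid <- valid & planes[[i]]$valid_mask
  }
  new_transmittance_stack(vals, wl, valid,
                          n_clamped_high = sum(vapply(planes, `[[`, 0, "n_clamped_high")),
                          n_clamped_low = sum(vapply(planes, `[[`, 0, "n_clamped_low")))
}

new_transmittance_stack <- function(values, wavelengths_nm, valid_mask,
                                    n_clamped_high = 0L, n_clamped_low = 0L) {
  structure(list(values = values, wavelengths_nm = wavelengths_nm,
                 valid_mask = valid_mask, n_clamped_high = n_clamped_high,
                 n_clamped_low = n_clamped_low),
            class = "transmittance_stack")
}

#' @export
print.transmittance_stack <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<transmittance_stack> %d x %d frame, %d wavelengths (%s nm), %d/%d pixels valid\n",
              d[1], d[2], d[3], paste(x$wavelengths_nm, collapse = ", "),
              sum(x$valid_mask), length(x$valid_mask)))
  invisible(x)
}

#' Natural logarithm of the inverse transmittance
#'
#' Elementwise `ln(1 / T)`, the left-hand side of the per-pixel linear system
#' `mu %*% d = ln(1/T)`. Nonnegative and finite wherever the stack is valid,
#' because transmittance is clamped into `(eps, 1]`.
#'
#' @param stack A [transmittance_stack()].
#' @return A `loginv_field` with the same shape, wavelengths and validity
#'   mask as `stack`.
#' @export
log_inverse_transmittance <- function(stack) {
  stopifnot(inherits(stack, "transmittance_stack"))
  vals <- -log(stack$values)
  structure(list(values = vals, wavelengths_nm = stack$wavelengths_nm,
                 valid_mask = stack$valid_mask),
            class = "loginv_field")
}

#' Forward Beer-Lambert attenuation through stacked layers
#'
#' Transmittance of a light ray crossing k homogeneous layers:
#' `T = exp(-sum(mu_i * d_i))`, the multiplicative composition of the
#' per-layer Beer-Lambert factors.
#'
#' @param thicknesses Numeric vector of layer thicknesses in cm (>= 0).
#' @param coefficients Numeric vector of attenuation coefficients in cm^-1
#'   (> 0), same length.
#' @return Transmittance scalar in (0, 1].
#' @examples
#' forward_attenuation(0.5, 2)  # exp(-1)
#' @export
forward_attenuation <- function(thicknesses, coefficients) {
  if (length(thicknesses) != length(coefficients))
    stop("thicknesses and coefficients must have equal length")
  if (any(thicknesses < 0)) stop("negative thickness")
  if (any(coefficients <= 0)) stop("coefficients must be positive")
  exp(-sum(coefficients * thicknesses))
}

#' Per-tissue thickness maps
#'
#' The decomposition output: one 2-D thickness image per tissue, in cm,
#' stored as a rows x cols x k array whose third dimension follows the
#' attenuation matrix column (tissue) order. `raw_values` keeps the solver
#' output before any negativity clipping.
#'
#' @param values rows x cols x k numeric array, cm.
#' @param tissue_labels Character vector of k tissue names.
#' @param raw_values Same-shaped array of unclipped solutions; defaults to
#'   `values`.
#' @param valid_mask Logical rows x cols matrix; defaults to all finite.
#' @return An object of class `thickness_maps`.
#' @export
thickness_maps <- function(values, tissue_labels, raw_values = values,
                           valid_mask = NULL) {
  if (length(dim(values)) != 3L || dim(values)[3L] != length(tissue_labels))
    stop("values must be a rows x cols x k array matching tissue_labels")
  if (!identical(dim(raw_values), dim(values)))
    stop("raw_values shape must match values")
  if (any(values < 0, na.rm = TRUE)) stop("clipped thickness values must be >= 0")
  if (is.null(valid_mask))
    valid_mask <- apply(is.finite(values), c(1, 2), all)
  dimnames(values)[[3]] <- tissue_labels
  dimnames(raw_values)[[3]] <- tissue_labels
  structure(list(values = values, tissue_labels = tissue_labels,
                 raw_values = raw_values, valid_mask = valid_mask),
            class = "thickness_maps")
}

#' @export
print.thickness_maps <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<thickness_maps> %d x %d frame, tissues: %s; range [%g, %g] cm\n",
              d[1], d[2], paste(x$tissue_labels, collapse = ", "),
              min(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE)))
  invisible(x)
}
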