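#' Phantom scene specification
#'
#' Declares a synthetic specimen and its acquisition: tissue regions
#' (axis-aligned rectangles or ellipses, thickness in cm), optional
#' full-frame overlay layers, a Gaussian illumination beam, multiplicative
#' speckle and additive read noise, camera bit depth, saturation and seed.
#' All pixel coordinates are 0-based, `x` = column, `y` = row.
#'
#' @param frame_shape `c(rows, cols)` in pixels.
#' @param tissue_labels Ordered tissue names (defines the map order).
#' @param regions List of regions; each a list with `tissue`, `shape`
#'   (`"rectangle"` with `x, y, width, height` or `"ellipse"` with
#'   `cx, cy, rx, ry`), and `thickness_cm`.
#' @param overlay_layers List of `list(tissue =, thickness_cm =)` uniform
#'   layers covering the whole frame.
#' @param beam `list(amplitude =, center = c(x0, y0), sigma =)` in counts /
#'   pixels.
#' @param noise `list(speckle_sigma =, read_sigma =)`: lognormal sigma of
#'   the multiplicative speckle (median 1) and the Gaussian read noise sd in
#'   counts. Defaults 0.02 and 2 counts, the package's stand-in for a
#'   diffuser-suppressed coherent source and a cooled CMOS camera.
#' @param bit_depth Camera bit depth, default 16.
#' @param saturation_level Clipping count, default full scale.
#' @param seed Integer RNG seed; identical spec + seed gives bit-identical
#'   output.
#' @param quantize Round counts to integers (default `TRUE`); disable for
#'   exact round-trip studies.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(frame_shape, tissue_labels, regions = list(),
                         overlay_layers = list(),
                         beam = list(amplitude = 0.75 * (2^16 - 1),
                                     center = (rev(frame_shape) - 1) / 2,
                                     sigma = 0.5 * min(frame_shape)),
                         noise = list(speckle_sigma = 0.02, read_sigma = 2),
                         bit_depth = 16L,
                         saturation_level = 2^bit_depth - 1,
                         seed = 1L, quantize = TRUE) {
  stopifnot(length(frame_shape) == 2, all(frame_shape >= 1),
            length(tissue_labels) >= 1, beam$sigma > 0,
            noise$speckle_sigma >= 0, noise$read_sigma >= 0)
  for (r in regions) {
    if (!r$tissue %in% tissue_labels)
      stop("region references unknown tissue label '", r$tissue, "'")
    if (r$thickness_cm < 0) stop("region thickness must be >= 0")
  }
  for (o in overlay_layers) {
    if (!o$tissue %in% tissue_labels)
      stop("overlay references unknown tissue label '", o$tissue, "'")
    if (o$thickness_cm < 0) stop("overlay thickness must be >= 0")
  }
  structure(list(frame_shape = as.integer(frame_shape),
                 tissue_labels = tissue_labels, regions = regions,
                 overlay_layers = overlay_layers, beam = beam, noise = noise,
                 bit_depth = as.integer(bit_depth),
                 saturation_level = saturation_level,
                 seed = as.integer(seed), quantize = isTRUE(quantize)),
            class = "phantom_spec")
}

#' Gaussian illumination beam profile
#'
#' Circular Gaussian `A * exp(-((x - x0)^2 + (y - y0)^2) / (2 sigma^2))`
#' evaluated at pixel centers; `x` is the 0-based column index and `y` the
#' 0-based row index.
#'
#' @param frame_shape `c(rows, cols)`.
#' @param amplitude Peak counts `A`.
#' @param center `c(x0, y0)` in pixels.
#' @param sigma Beam width in pixels, > 0.
#' @return Numeric rows x cols matrix of counts.
#' @export
gaussian_beam <- function(frame_shape, amplitude, center, sigma) {
  stopifnot(sigma > 0)
  y <- seq_len(frame_shape[1]) - 1
  x <- seq_len(frame_shape[2]) - 1
  r2 <- outer((y - center[2])^2, (x - center[1])^2, `+`)
  amplitude * exp(-r2 / (2 * sigma^2))
}

#' Rasterize a phantom spec into ground-truth thickness maps
#'
#' Each tissue's map is the sum of its regions' thicknesses (regions of the
#' same tissue stack additively) plus any full-frame overlay thickness;
#' pixels in no region and no overlay are 0.
#'
#' @param spec A [phantom_spec()].
#' @return A [thickness_maps()] in the spec's tissue order.
#' @export
make_thickness_maps <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  M <- spec$frame_shape[1]; N <- spec$frame_shape[2]
  k <- length(spec$tissue_labels)
  vals <- array(0, c(M, N, k))
  for (r in spec$regions) {
    j <- match(r$tissue, spec$tissue_labels)
    mask <- region_mask(r, M, N)
    plane <- vals[, , j]
    plane[mask] <- plane[mask] + r$thickness_cm
    vals[, , j] <- plane
  }
  for (o in spec$overlay_layers) {
    j <- match(o$tissue, spec$tissue_labels)
    vals[, , j] <- vals[, , j] + o$thickness_cm
  }
  thickness_maps(vals, spec$tissue_labels,
                 valid_mask = matrix(TRUE, M, N))
}

region_mask <- function(r, M, N) {
  y <- seq_len(M) - 1
  x <- seq_len(N) - 1
  if (r$shape == "rectangle") {
    g <- r
    if (g$x < 0 || g$y < 0 || g$x + g$width > N || g$y + g$height > M)
      stop("rectangle region outside frame bounds")
    outer(y >= g$y & y <= g$y + g$height - 1,
          x >= g$x & x <= g$x + g$width - 1, `&`)
  } else if (r$shape == "ellipse") {
    g <- r
    outer(((y - g$cy) / g$ry)^2, ((x - g$cx) / g$rx)^2, `+`) <= 1
  } else stop("unknown region shape '", r$shape, "'")
}

#' Render a phantom into camera images
#'
#' Simulates the acquisition: for each wavelength, the ideal object image is
#' the beam attenuated per pixel by `exp(-sum_t mu[lambda, t] * d_t(x, y))`;
#' both object and reference (zero-thickness) exposures then receive
#' independent multiplicative lognormal speckle and additive Gaussian read
#' noise, are clipped to `[0, saturation_level]`, and (optionally) quantized
#' to integer counts with round-half-away-from-zero. Deterministic for a
#' fixed spec seed.
#'
#' @param maps Ground-truth [thickness_maps()]; tissue order must equal the
#'   matrix column order.
#' @param matrix An [attenuation_matrix()].
#' @param spec The [phantom_spec()] providing beam, noise, camera and seed.
#' @return A `phantom_output`: `ground_truth`, `reference_images`,
#'   `object_images` (lists of [intensity_image()] per wavelength), `spec`.
#' @export
render_stack <- function(maps, matrix, spec) {
  stopifnot(inherits(maps, "thickness_maps"),
            inherits(matrix, "attenuation_matrix"),
            inherits(spec, "phantom_spec"))
  if (!identical(maps$tissue_labels, matrix$tissue_labels))
    stop("tissue label order mismatch: maps (",
         paste(maps$tissue_labels, collapse = ", "), ") vs matrix columns (",
         paste(matrix$tissue_labels, collapse = ", "), ")")
  M <- spec$frame_shape[1]; N <- spec$frame_shape[2]
  if (!identical(dim(maps$values)[1:2], c(M, N)))
    stop("maps frame size does not match the spec")
  beam <- gaussian_beam(spec$frame_shape, spec$beam$amplitude,
                        spec$beam$center, spec$beam$sigma)
  k <- length(matrix$wavelengths_nm)
  set.seed(spec$seed)
  refs <- objs <- vector("list", k)
  for (i in seq_len(k)) {
    optical_depth <- matrix(0, M, N)
    for (j in seq_along(matrix$tissue_labels))
      optical_depth <- optical_depth + matrix$values[i, j] * maps$values[, , j]
    ideal_obj <- beam * exp(-optical_depth)
    refs[[i]] <- camera_exposure(beam, spec, matrix$wavelengths_nm[i])
    objs[[i]] <- camera_exposure(ideal_obj, spec, matrix$wavelengths_nm[i])
  }
  structure(list(ground_truth = maps, reference_images = refs,
                 object_images = objs, spec = spec),
            class = "phantom_output")
}

# One exposure through the camera model: speckle, read noise, clip, quantize.
camera_exposure <- function(ideal, spec, wavelength_nm) {
  M <- nrow(ideal); N <- ncol(ideal)
  img <- ideal
  if (spec$noise$speckle_sigma > 0)
    img <- img * matrix(stats::rlnorm(M * N, meanlog = 0,
                                      sdlog = spec$noise$speckle_sigma), M, N)
  if (spec$noise$read_sigma > 0)
    img <- img + matrix(stats::rnorm(M * N, sd = spec$noise$read_sigma), M, N)
  img <- pmin(pmax(img, 0), spec$saturation_level)
  if (spec$quantize) img <- round_half_away(img)
  intensity_image(img, bit_depth = spec$bit_depth,
                  wavelength_nm = wavelength_nm,
                  saturation_level = spec$saturation_level)
}

#' @export
print.phantom_output <- function(x, ...) {
  cat(sprintf("<phantom_output> %d x %d frame, %d wavelengths, tissues: %s, seed %d\n",
              x$spec$frame_shape[1], x$spec$frame_shape[2],
              length(x$object_images),
              paste(x$spec$tissue_labels, collapse = ", "), x$spec$seed))
  invisible(x)
}

#' Built-in phantom presets
#'
#' Two scene layouts mirroring the package's reference experiments with
#' chicken tissue:
#' * `"side_by_side"` — three rectangular blocks of meat (0.5 cm), bone
#'   (0.3 cm) and skin (0.2 cm) arranged side by side on an empty
#'   background.
#' * `"skin_overlay"` — the same three blocks completely covered by a
#'   uniform 0.1 cm skin layer, the occluded-specimen scenario.
#'
#' Block geometry scales with the frame; the beam peaks at 75% of
#' saturation at the frame center with sigma half the frame side, so every
#' pixel stays above the dark floor and below saturation.
#'
#' @param name `"side_by_side"` or `"skin_overlay"`.
#' @param frame_shape `c(rows, cols)`, default `c(256, 256)`.
#' @param seed RNG seed.
#' @param noise,quantize Passed to [phantom_spec()]; defaults are the
#'   standard acquisition model (speckle sigma 0.02, read sigma 2 counts,
#'   quantized).
#' @return A [phantom_spec()] with tissues `meat`, `bone`, `skin`.
#' @export
phantom_preset <- function(name = c("side_by_side", "skin_overlay"),
                           frame_shape = c(256L, 256L), seed = 1L,
                           noise = list(speckle_sigma = 0.02, read_sigma = 2),
                           quantize = TRUE) {
  name <- match.arg(name)
  M <- frame_shape[1]; N <- frame_shape[2]
  block <- function(tissue, x0_frac, thickness) {
    list(tissue = tissue, shape = "rectangle",
         x = round(x0_frac * N), y = round(0.25 * M),
         width = round(0.25 * N), height = round(0.5 * M),
         thickness_cm = thickness)
  }
  regions <- list(block("meat", 0.06, 0.5),
                  block("bone", 0.375, 0.3),
                  block("skin", 0.69, 0.2))
  overlays <- if (name == "skin_overlay")
    list(list(tissue = "skin", thickness_cm = 0.1)) else list()
  phantom_spec(frame_shape = frame_shape,
               tissue_labels = c("meat", "bone", "skin"),
               regions = regions, overlay_layers = overlays,
               beam = list(amplitude = 0.75 * (2^16 - 1),
                           center = (rev(frame_shape) - 1) / 2,
                           sigma = 0.5 * min(frame_shape)),
               noise = noise, bit_depth = 16L, seed = seed,
               quantize = quantize)
}

#' Simulate a phantom end to end
#'
#' Convenience wrapper: rasterize the spec's ground-truth maps and render
#' the camera images with the given attenuation matrix.
#'
#' @param spec A [phantom_spec()].
#' @param matrix An [attenuation_matrix()]; defaults to the packaged
#'   chicken-tissue matrix when the spec uses its tissues.
#' @return A `phantom_output`.
#' @export
simulate_phantom <- function(spec, matrix = chicken_attenuation_matrix()) {
  maps <- make_thickness_maps(spec)
  render_stack(maps, matrix, spec)
}

#' Decompose a phantom output back into thickness maps
#'
#' Closes the loop: transmittance from the rendered object/reference pairs,
#' log-inverse transform, per-pixel solve against the same matrix.
#'
#' @param output A `phantom_output`.
#' @param matrix The [attenuation_matrix()] to invert.
#' @param dark_floor_frac,eps Passed to [transmittance_stack()].
#' @return A `decomposition_result`.
#' @export
decompose_phantom <- function(output, matrix = chicken_attenuation_matrix(),
                              dark_floor_frac = 0.01, eps = 1e-6) {
  stack <- transmittance_stack(output$object_images, output$reference_images,
                               dark_floor_frac = dark_floor_frac, eps = eps)
  decompose_stack(log_inverse_transmittance(stack), matrix)
}
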