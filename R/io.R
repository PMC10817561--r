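#' Read a single-channel raster image
#'
#' Reads 8- or 16-bit grayscale TIFF or PNG into an [intensity_image()] of
#' integer counts; the bit depth is inferred from the file and recorded.
#' Multi-channel (color) inputs are rejected, not converted: the acquisition
#' model is monochromatic.
#'
#' @param path Image path (.tif/.tiff/.png).
#' @param wavelength_nm Wavelength to record on the image, optional.
#' @return An [intensity_image()].
#' @export
read_image <- function(path, wavelength_nm = NA_real_) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    x <- tiff::readTIFF(path, as.is = TRUE, info = TRUE)
    bits <- attr(x, "bits.per.sample")
    if (is.null(bits)) bits <- 8L
  } else if (ext == "png") {
    x <- png::readPNG(path, info = TRUE)
    bits <- attr(x, "info")$bit.depth
    x <- x * (2^bits - 1)  # readPNG scales to [0, 1]
  } else stop("unsupported image format: .", ext)
  if (length(dim(x)) == 3L)
    stop("multi-channel image with ", dim(x)[3L],
         " channels; only single-channel images are supported")
  attributes(x) <- list(dim = dim(x))
  intensity_image(round_half_away(x), bit_depth = bits,
                  wavelength_nm = wavelength_nm)
}

#' Write a single-channel raster image
#'
#' Writes integer counts losslessly: TIFF at the image's bit depth (8 or
#' 16); PNG at 8 bits.
#'
#' @param img An [intensity_image()].
#' @param path Output path (.tif/.tiff/.png).
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  stopifnot(inherits(img, "intensity_image"))
  ext <- tolower(tools::file_ext(path))
  full <- 2^img$bit_depth - 1
  if (ext %in% c("tif", "tiff")) {
    if (!img$bit_depth %in% c(8L, 16L))
      stop("TIFF output supports 8- or 16-bit images")
    tiff::writeTIFF(img$pixels / full, path, bits.per.sample = img$bit_depth)
  } else if (ext == "png") {
    if (img$bit_depth != 8L)
      stop("PNG output supports 8-bit images; use TIFF for ", img$bit_depth, "-bit")
    png::writePNG(img$pixels / full, path)
  } else stop("unsupported image format: .", ext)
  invisible(path)
}

#' Write / read thickness maps as 32-bit float TIFFs
#'
#' One float TIFF per tissue plus a JSON manifest. Float TIFF samples must
#' lie in `[0, 1]`, so each map is stored divided by a per-tissue scale
#' (cm per stored unit) recorded in the manifest; reading undoes the
#' scaling. No-data pixels are stored as 0 and restored from the manifest's
#' validity run-length encoding.
#'
#' @param maps A [thickness_maps()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_thickness_maps <- function(maps, dir) {
  stopifnot(inherits(maps, "thickness_maps"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  scales <- numeric(length(maps$tissue_labels))
  files <- character(length(maps$tissue_labels))
  for (j in seq_along(maps$tissue_labels)) {
    plane <- maps$values[, , j]
    mx <- max(plane[is.finite(plane)], 0)
    scales[j] <- if (mx > 0) mx else 1
    plane[!is.finite(plane)] <- 0
    files[j] <- paste0("thickness_", maps$tissue_labels[j], ".tif")
    tiff::writeTIFF(plane / scales[j], file.path(dir, files[j]),
                    bits.per.sample = 32L, reduce = FALSE)
  }
  manifest <- list(tissue_labels = maps$tissue_labels, files = files,
                   scale_cm = scales,
                   valid_rle = unclass(rle(as.vector(maps$valid_mask))),
                   frame_shape = dim(maps$valid_mask))
  mpath <- file.path(dir, "thickness_manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = FALSE, digits = NA)
  invisible(mpath)
}

#' @param dir Directory written by [write_thickness_maps()].
#' @rdname write_thickness_maps
#' @export
read_thickness_maps <- function(dir) {
  man <- jsonlite::fromJSON(file.path(dir, "thickness_manifest.json"))
  shp <- man$frame_shape
  k <- length(man$tissue_labels)
  valid <- matrix(inverse.rle(structure(list(lengths = man$valid_rle$lengths,
                                             values = man$valid_rle$values),
                                        class = "rle")),
                  shp[1], shp[2])
  vals <- array(NA_real_, c(shp[1], shp[2], k))
  for (j in seq_len(k)) {
    plane <- tiff::readTIFF(file.path(dir, man$files[j])) * man$scale_cm[j]
    plane[!valid] <- NA_real_
    vals[, , j] <- plane
  }
  thickness_maps(vals, man$tissue_labels, valid_mask = valid)
}

#' Read a run configuration from YAML
#'
#' Validates the minimal structure used by the command-line interface:
#' a `mode`, file paths that must exist, and positive tolerances.
#'
#' @param path YAML file.
#' @return The configuration list, class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$mode) &&
      !cfg$mode %in% c("simulate", "characterize", "decompose", "evaluate"))
    stop("unknown mode '", cfg$mode, "'")
  for (p in cfg$inputs)
    if (!file.exists(p)) stop("input path does not exist: ", p)
  for (tol in c("singularity_tol", "condition_warn", "dark_floor_frac", "eps"))
    if (!is.null(cfg[[tol]]) && cfg[[tol]] <= 0)
      stop(tol, " must be positive")
  structure(cfg, class = c("run_config", "list"))
}

#' @param cfg A `run_config`.
#' @rdname read_run_config
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
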