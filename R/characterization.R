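#' Homogeneous-specimen characterization sample
#'
#' One measurement used to characterize a tissue's attenuation coefficient:
#' an object/reference image pair of a homogeneous specimen of known uniform
#' thickness, at one wavelength.
#'
#' @param tissue_label Tissue name.
#' @param wavelength_nm Illumination wavelength (nm), positive.
#' @param thickness_cm Known uniform specimen thickness in cm, positive.
#' @param object_img,reference_img [intensity_image()] pair.
#' @return An object of class `characterization_sample`.
#' @export
characterization_sample <- function(tissue_label, wavelength_nm, thickness_cm,
                                    object_img, reference_img) {
  if (thickness_cm <= 0) stop("thickness_cm must be positive")
  stopifnot(inherits(object_img, "intensity_image"),
            inherits(reference_img, "intensity_image"))
  if (!identical(dim(object_img$pixels), dim(reference_img$pixels)))
    stop("object and reference images must have the same shape")
  structure(list(tissue_label = tissue_label, wavelength_nm = wavelength_nm,
                 thickness_cm = thickness_cm, object_img = object_img,
                 reference_img = reference_img),
            class = "characterization_sample")
}

#' Per-pixel attenuation coefficient plane
#'
#' For a homogeneous specimen of known thickness d, the attenuation
#' coefficient at each pixel is `mu(x, y) = -ln(T(x, y)) / d`; for a good
#' specimen the result is a near-flat plane whose height is the tissue's
#' coefficient at that wavelength.
#'
#' @param sample A [characterization_sample()].
#' @param dark_floor_frac,eps Passed to [transmittance()].
#' @return List with `values` (matrix, cm^-1, `NA` where invalid) and
#'   `valid_mask`.
#' @export
attenuation_plane <- function(sample, dark_floor_frac = 0.01, eps = 1e-6) {
  stopifnot(inherits(sample, "characterization_sample"))
  if (sample$thickness_cm <= 0) stop("thickness must be positive")
  tr <- transmittance(sample$object_img, sample$reference_img,
                      dark_floor_frac = dark_floor_frac, eps = eps)
  list(values = -log(tr$values) / sample$thickness_cm,
       valid_mask = tr$valid_mask)
}

#' Collapse an attenuation plane to a single coefficient
#'
#' Arithmetic mean of the per-pixel coefficients over the selected pixels,
#' with the standard deviation for a plus/minus report. The default
#' characterization mask elsewhere in the package is the central crop of the
#' frame, where the Gaussian beam is bright.
#'
#' @param plane Numeric matrix of per-pixel coefficients (cm^-1).
#' @param mask Logical matrix selecting at least one pixel.
#' @return List with `mean`, `sd` (both cm^-1) and `n` pixels used.
#' @export
mean_attenuation <- function(plane, mask) {
  stopifnot(is.matrix(plane), is.logical(mask),
            identical(dim(plane), dim(mask)))
  v <- plane[mask]
  v <- v[is.finite(v)]
  if (length(v) == 0L) stop("mask selects no valid pixel")
  list(mean = mean(v), sd = stats::sd(v), n = length(v))
}

#' Central-crop characterization mask
#'
#' Logical mask selecting the central `frac` x `frac` portion of a frame,
#' used to keep characterization away from the dim edges of a Gaussian beam.
#'
#' @param frame_shape `c(rows, cols)`.
#' @param frac Side fraction of the crop, default 0.5.
#' @return Logical matrix.
#' @export
central_mask <- function(frame_shape, frac = 0.5) {
  m <- matrix(FALSE, frame_shape[1], frame_shape[2])
  rh <- floor(frame_shape[1] * frac / 2)
  ch <- floor(frame_shape[2] * frac / 2)
  rc <- (frame_shape[1] + 1) / 2
  cc <- (frame_shape[2] + 1) / 2
  rows <- max(1, ceiling(rc - rh)):min(frame_shape[1], floor(rc + rh))
  cols <- max(1, ceiling(cc - ch)):min(frame_shape[2], floor(cc + ch))
  m[rows, cols] <- TRUE
  m
}

#' Asymptotic regression of coefficient versus specimen thickness
#'
#' Thin specimens are biased by their transparent case; as the specimen
#' thickens the measured coefficient approaches the tissue's true value. The
#' model `mu(d) = beta0 + beta1 / d^exponent` captures this: `beta0` is the
#' asymptote (the case-free coefficient estimate) and `beta1` scales the
#' thin-specimen bias. The model is linear in the parameters, so the fit is
#' the exact linear least-squares solution on the regressor `d^-exponent`.
#'
#' @param thicknesses Numeric vector of specimen thicknesses (cm), at least
#'   two distinct values.
#' @param coefficients Measured coefficients (cm^-1), same length.
#' @param exponent Power of the inverse-thickness term, default 3.
#' @return An `asymptotic_fit` list: `beta0`, `beta1`, `residual_sse`,
#'   `n_points`, `stderr_beta0` (`NA` with only 2 points).
#' @examples
#' fit_asymptotic(c(0.5, 1), c(3.4, 3.05))  # beta0 = 3, beta1 = 0.05
#' @export
fit_asymptotic <- function(thicknesses, coefficients, exponent = 3) {
  if (length(thicknesses) != length(coefficients))
    stop("thicknesses and coefficients must have equal length")
  if (length(thicknesses) < 2L)
    stop("at least two points are required")
  if (length(unique(thicknesses)) < 2L)
    stop("all thicknesses identical: the design matrix is singular")
  if (any(thicknesses <= 0)) stop("thicknesses must be positive")
  x <- thicknesses^(-exponent)
  fit <- stats::lm(coefficients ~ x)
  cf <- stats::coef(fit)
  # a noise-free fit is "essentially perfect" and lm warns on its vcov;
  # the point estimate is still what we want
  se <- tryCatch(suppressWarnings(sqrt(diag(stats::vcov(fit)))[1]),
                 error = function(e) NA_real_)
  structure(list(beta0 = unname(cf[1]), beta1 = unname(cf[2]),
                 residual_sse = sum(stats::residuals(fit)^2),
                 n_points = length(thicknesses),
                 stderr_beta0 = unname(se), exponent = exponent),
            class = "asymptotic_fit")
}

#' @export
print.asymptotic_fit <- function(x, ...) {
  cat(sprintf("<asymptotic_fit> mu(d) = %.6g + %.6g / d^%g  (n = %d, SSE = %.3g)\n",
              x$beta0, x$beta1, x$exponent, x$n_points, x$residual_sse))
  invisible(x)
}

#' Tissue attenuation coefficient matrix
#'
#' The k x k matrix at the heart of the decomposition: rows indexed by
#' illumination wavelength, columns by tissue, entries in cm^-1. Its inverse
#' maps the log-inverse-transmittance vector at a pixel to the tissue
#' thickness vector.
#'
#' @param values k x k numeric matrix, all entries positive and finite.
#' @param wavelengths_nm Numeric vector of k wavelengths (row order).
#' @param tissue_labels Character vector of k tissue names (column order).
#' @param uncertainties Optional k x k matrix of plus/minus values.
#' @return An object of class `attenuation_matrix`.
#' @export
attenuation_matrix <- function(values, wavelengths_nm, tissue_labels,
                               uncertainties = NULL) {
  values <- as.matrix(values)
  k <- length(wavelengths_nm)
  if (nrow(values) != k || ncol(values) != length(tissue_labels))
    stop("values must be length(wavelengths_nm) x length(tissue_labels)")
  if (nrow(values) != ncol(values)) stop("attenuation matrix must be square")
  if (any(!is.finite(values)) || any(values < 0))
    stop("all coefficients must be nonnegative and finite")
  if (!is.null(uncertainties) && !identical(dim(as.matrix(uncertainties)), dim(values)))
    stop("uncertainties shape must match values")
  dimnames(values) <- list(format(wavelengths_nm, trim = TRUE), tissue_labels)
  structure(list(values = values, wavelengths_nm = wavelengths_nm,
                 tissue_labels = tissue_labels, uncertainties = uncertainties),
            class = "attenuation_matrix")
}

#' @export
print.attenuation_matrix <- function(x, ...) {
  cat(sprintf("<attenuation_matrix> %d x %d (cm^-1), rows = wavelength (nm), cols = tissue\n",
              nrow(x$values), ncol(x$values)))
  print(x$values)
  invisible(x)
}

#' Assemble an attenuation matrix from per-cell coefficient entries
#'
#' Takes a long-format table of characterized coefficients, one row per
#' (wavelength, tissue) cell, and arranges them into the square matrix with
#' rows ordered by the given wavelength order and columns by the given
#' tissue order. The grid must be complete and free of duplicates.
#'
#' @param entries Data frame with columns `wavelength_nm`, `tissue`,
#'   `mu_cm_inv` and optionally `sd`.
#' @param wavelength_order,tissue_order Row/column orders; default to order
#'   of first appearance in `entries`.
#' @return An [attenuation_matrix()].
#' @export
build_attenuation_matrix <- function(entries,
                                     wavelength_order = unique(entries$wavelength_nm),
                                     tissue_order = unique(entries$tissue)) {
  stopifnot(is.data.frame(entries),
            all(c("wavelength_nm", "tissue", "mu_cm_inv") %in% names(entries)))
  k <- length(wavelength_order)
  if (length(tissue_order) != k)
    stop("need as many tissues as wavelengths for a square matrix")
  key <- paste(entries$wavelength_nm, entries$tissue, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate cell(s): ", paste(unique(gsub("\r", " / ", key[duplicated(key)])),
                                      collapse = ", "))
  vals <- matrix(NA_real_, k, k)
  unc <- matrix(NA_real_, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    hit <- which(entries$wavelength_nm == wavelength_order[i] &
                   entries$tissue == tissue_order[j])
    if (length(hit) == 0L)
      stop("missing cell: wavelength ", wavelength_order[i],
           " nm, tissue '", tissue_order[j], "'")
    vals[i, j] <- entries$mu_cm_inv[hit]
    unc[i, j] <- if ("sd" %in% names(entries)) entries$sd[hit] else NA_real_
  }
  attenuation_matrix(vals, wavelength_order, tissue_order,
                     uncertainties = if (all(is.na(unc))) NULL else unc)
}

#' Invertibility diagnostics of an attenuation matrix
#'
#' Reports the determinant, the (exact, 2-norm) condition number, and an
#' invertibility verdict. Rows measured at nearby wavelengths tend toward
#' linear dependence; the resulting small determinant / large condition
#' number amplifies noise in the per-pixel solve, so a warning is attached
#' when conditioning exceeds the threshold.
#'
#' @param matrix An [attenuation_matrix()] or plain square matrix.
#' @param singularity_tol `abs(det)` at or below this is reported as
#'   non-invertible. Default 1e-10.
#' @param condition_warn Condition-number warning threshold, default 1e3.
#' @return A `matrix_diagnostics` list: `determinant` (cm^-k for a k x k
#'   matrix of cm^-1 entries), `condition_number`, `invertible`, `warnings`.
#' @export
matrix_diagnostics <- function(matrix, singularity_tol = 1e-10,
                               condition_warn = 1e3) {
  vals <- if (inherits(matrix, "attenuation_matrix")) matrix$values else as.matrix(matrix)
  if (nrow(vals) != ncol(vals)) stop("matrix must be square")
  dt <- det(vals)
  invertible <- abs(dt) > singularity_tol
  cond <- if (invertible) kappa(vals, exact = TRUE) else Inf
  warnings <- character(0)
  if (!invertible)
    warnings <- c(warnings, sprintf(
      "matrix is numerically singular (|determinant| = %.3g <= %.3g)",
      abs(dt), singularity_tol))
  else if (cond > condition_warn)
    warnings <- c(warnings, sprintf(
      paste0("condition number %.3g exceeds %.3g: rows/columns are near",
             " linear dependence and the decomposition will amplify noise"),
      cond, condition_warn))
  structure(list(determinant = dt, condition_number = cond,
                 invertible = invertible, warnings = warnings),
            class = "matrix_diagnostics")
}

#' @export
print.matrix_diagnostics <- function(x, ...) {
  cat(sprintf("<matrix_diagnostics> determinant = %.6g, condition = %.6g, invertible: %s\n",
              x$determinant, x$condition_number, x$invertible))
  for (w in x$warnings) cat(" warning:", w, "\n")
  invisible(x)
}

#' Characterize a full attenuation matrix from specimen samples
#'
#' Runs the whole characterization pipeline: per-sample attenuation planes
#' averaged over the central mask, an optional asymptotic fit across
#' specimen thicknesses per (wavelength, tissue) cell, and assembly into the
#' square matrix.
#'
#' @param samples List of [characterization_sample()]s covering every
#'   (wavelength, tissue) cell, possibly at several thicknesses each.
#' @param use_asymptote If `TRUE` (default) and a cell has >= 2 distinct
#'   thicknesses, the cell's coefficient is the asymptote `beta0` of
#'   [fit_asymptotic()]; otherwise the mean over that cell's samples.
#' @param mask_frac Central-crop fraction for [central_mask()], default 0.5.
#' @param exponent Passed to [fit_asymptotic()].
#' @return List with the `matrix` ([attenuation_matrix()]), its
#'   `diagnostics`, and the long-format `table` of per-cell results.
#' @export
characterize_matrix <- function(samples, use_asymptote = TRUE, mask_frac = 0.5,
                                exponent = 3) {
  stopifnot(length(samples) >= 1)
  per <- lapply(samples, function(s) {
    pl <- attenuation_plane(s)
    mask <- central_mask(dim(pl$values), mask_frac) & pl$valid_mask
    m <- mean_attenuation(pl$values, mask)
    data.frame(wavelength_nm = s$wavelength_nm, tissue = s$tissue_label,
               thickness_cm = s$thickness_cm, mu_cm_inv = m$mean, sd = m$sd)
  })
  per <- do.call(rbind, per)
  cells <- unique(per[c("wavelength_nm", "tissue")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sub <- per[per$wavelength_nm == cells$wavelength_nm[i] &
                 per$tissue == cells$tissue[i], ]
    if (use_asymptote && length(unique(sub$thickness_cm)) >= 2L) {
      fit <- fit_asymptotic(sub$thickness_cm, sub$mu_cm_inv, exponent = exponent)
      data.frame(wavelength_nm = cells$wavelength_nm[i], tissue = cells$tissue[i],
                 mu_cm_inv = fit$beta0,
                 sd = if (is.na(fit$stderr_beta0)) mean(sub$sd) else fit$stderr_beta0)
    } else {
      data.frame(wavelength_nm = cells$wavelength_nm[i], tissue = cells$tissue[i],
                 mu_cm_inv = mean(sub$mu_cm_inv), sd = mean(sub$sd))
    }
  })
  tab <- do.call(rbind, rows)
  mat <- build_attenuation_matrix(tab)
  list(matrix = mat, diagnostics = matrix_diagnostics(mat), table = tab)
}

#' Published chicken-tissue NIR attenuation coefficient matrix
#'
#' The package's reference worked example: attenuation coefficients of
#' chicken meat, bone and skin characterized at 780, 808 and 980 nm
#' (asymptotic estimates, cm^-1), shipped as a CSV in `inst/extdata`. Its
#' determinant is small (about 0.087 cm^-3) because the three NIR
#' wavelengths are close together — the canonical illustration of the
#' conditioning diagnostics.
#'
#' @return An [attenuation_matrix()] with rows (780, 808, 980) nm and
#'   columns (meat, bone, skin).
#' @examples
#' m <- chicken_attenuation_matrix()
#' matrix_diagnostics(m)
#' @export
chicken_attenuation_matrix <- function() {
  path <- system.file("extdata", "chicken_attenuation_nir.csv",
                      package = "biodecomp", mustWork = TRUE)
  read_coefficient_table(path,
                         wavelength_order = c(780, 808, 980),
                         tissue_order = c("meat", "bone", "skin"))
}

#' Read / write coefficient tables
#'
#' Long-format CSV with columns `wavelength_nm, tissue, mu_cm_inv, sd`,
#' or the equivalent JSON array of records.
#'
#' @param path File path; format chosen by extension (.csv or .json).
#' @param wavelength_order,tissue_order Passed to
#'   [build_attenuation_matrix()].
#' @return `read_coefficient_table`: an [attenuation_matrix()].
#' @export
read_coefficient_table <- function(path, wavelength_order = NULL,
                                   tissue_order = NULL) {
  ext <- tolower(tools::file_ext(path))
  tab <- switch(ext,
                csv = utils::read.csv(path, stringsAsFactors = FALSE),
                json = as.data.frame(jsonlite::fromJSON(path)),
                stop("unsupported coefficient table format: .", ext))
  args <- list(entries = tab)
  if (!is.null(wavelength_order)) args$wavelength_order <- wavelength_order
  if (!is.null(tissue_order)) args$tissue_order <- tissue_order
  do.call(build_attenuation_matrix, args)
}

#' @param matrix An [attenuation_matrix()] to serialize.
#' @rdname read_coefficient_table
#' @export
write_coefficient_table <- function(matrix, path) {
  stopifnot(inherits(matrix, "attenuation_matrix"))
  k <- nrow(matrix$values)
  tab <- data.frame(
    wavelength_nm = rep(matrix$wavelengths_nm, each = k),
    tissue = rep(matrix$tissue_labels, times = k),
    mu_cm_inv = as.vector(t(matrix$values)),
    sd = if (is.null(matrix$uncertainties)) NA_real_
         else as.vector(t(matrix$uncertainties)))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         csv = utils::write.csv(tab, path, row.names = FALSE),
         json = jsonlite::write_json(tab, path, dataframe = "rows",
                                     auto_unbox = TRUE, digits = NA),
         stop("unsupported coefficient table format: .", ext))
  invisible(path)
}

#' Serialize a matrix plus its diagnostics to JSON
#'
#' @param matrix An [attenuation_matrix()].
#' @param path Output JSON path.
#' @param ... Passed to [matrix_diagnostics()].
#' @export
write_matrix_json <- function(matrix, path, ...) {
  stopifnot(inherits(matrix, "attenuation_matrix"))
  diag <- matrix_diagnostics(matrix, ...)
  jsonlite::write_json(list(
    wavelengths_nm = matrix$wavelengths_nm,
    tissue_labels = matrix$tissue_labels,
    values = matrix$values,
    uncertainties = matrix$uncertainties,
    determinant = diag$determinant,
    condition_number = diag$condition_number,
    invertible = diag$invertible,
    warnings = diag$warnings
  ), path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}
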