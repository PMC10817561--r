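#' Solve the Beer-Lambert system at a single pixel
#'
#' Solves `mu %*% d = ln(1/T)` for the tissue thickness vector `d` at one
#' pixel via a linear solve (never an explicitly formed inverse). Noise can
#' push components negative; the raw solution is returned alongside the
#' zero-clipped one.
#'
#' @param log_inv_vec Numeric vector of k values `ln(1/T_lambda)`, in matrix
#'   row (wavelength) order.
#' @param matrix An [attenuation_matrix()].
#' @param singularity_tol Passed to [matrix_diagnostics()].
#' @return List with `thickness` (clipped, cm) and `raw` (solver output).
#' @examples
#' m <- attenuation_matrix(diag(c(2, 3, 4)), c(780, 808, 980), c("a", "b", "c"))
#' decompose_pixel(c(1, 1.5, 2), m)$thickness  # 0.5 0.5 0.5
#' @export
decompose_pixel <- function(log_inv_vec, matrix, singularity_tol = 1e-10) {
  stopifnot(inherits(matrix, "attenuation_matrix"))
  if (length(log_inv_vec) != nrow(matrix$values))
    stop("log_inv_vec length must equal the matrix dimension")
  diag_ <- matrix_diagnostics(matrix, singularity_tol = singularity_tol)
  if (!diag_$invertible)
    stop(sprintf("attenuation matrix is singular: determinant = %.6g",
                 diag_$determinant))
  raw <- as.vector(solve(matrix$values, log_inv_vec))
  names(raw) <- matrix$tissue_labels
  list(thickness = pmax(raw, 0), raw = raw)
}

#' Decompose a whole log-inverse-transmittance field into thickness maps
#'
#' Applies the per-pixel solve at every valid pixel of the frame, using one
#' LU factorization of the attenuation matrix for all pixels. The field's
#' wavelength order must equal the matrix row order (checked by label; no
#' silent reordering). Invalid pixels become `NA` in every tissue map.
#'
#' @param field A `loginv_field` from [log_inverse_transmittance()].
#' @param matrix An [attenuation_matrix()] with rows matching the field's
#'   wavelengths in order.
#' @param singularity_tol Passed to [matrix_diagnostics()].
#' @return A `decomposition_result`: `thickness_maps` ([thickness_maps()]),
#'   `negatives_fraction` (fraction of valid pixels with any negative raw
#'   component), and the matrix `diagnostics`.
#' @export
decompose_stack <- function(field, matrix, singularity_tol = 1e-10) {
  stopifnot(inherits(field, "loginv_field"),
            inherits(matrix, "attenuation_matrix"))
  if (!isTRUE(all.equal(field$wavelengths_nm, matrix$wavelengths_nm)))
    stop("wavelength order mismatch: field has (",
         paste(field$wavelengths_nm, collapse = ", "), ") nm, matrix rows are (",
         paste(matrix$wavelengths_nm, collapse = ", "), ") nm")
  diag_ <- matrix_diagnostics(matrix, singularity_tol = singularity_tol)
  if (!diag_$invertible)
    stop(sprintf("attenuation matrix is singular: determinant = %.6g",
                 diag_$determinant))
  d <- dim(field$values)
  k <- d[3]
  npix <- d[1] * d[2]
  # one factorization applied to all pixels: B is k x npix
  B <- t(array(field$values, dim = c(npix, k)))
  B[is.na(B)] <- 0  # placeholder; these columns are masked out below
  D <- solve(matrix$values, B)
  raw <- array(t(D), dim = c(d[1], d[2], k))
  invalid <- !field$valid_mask
  for (j in seq_len(k)) {
    plane <- raw[, , j]
    plane[invalid] <- NA_real_
    raw[, , j] <- plane
  }
  n_valid <- sum(field$valid_mask)
  if (n_valid == 0L) {
    warning("no valid pixels in the field; negatives_fraction reported as 0")
    neg_frac <- 0
  } else {
    # float roundoff at zero-thickness pixels gives raw values of order
    # -1e-16 cm; only count negatives beyond numerical noise
    any_neg <- apply(raw < -1e-12, c(1, 2), any)
    neg_frac <- sum(any_neg & field$valid_mask, na.rm = TRUE) / n_valid
  }
  maps <- thickness_maps(values = pmax(raw, 0), tissue_labels = matrix$tissue_labels,
                         raw_values = raw, valid_mask = field$valid_mask)
  structure(list(thickness_maps = maps, negatives_fraction = neg_frac,
                 diagnostics = diag_),
            class = "decomposition_result")
}

#' @export
print.decomposition_result <- function(x, ...) {
  cat("<decomposition_result>\n")
  print(x$thickness_maps)
  cat(sprintf("  negatives_fraction = %.4g; determinant = %.6g; condition = %.6g\n",
              x$negatives_fraction, x$diagnostics$determinant,
              x$diagnostics$condition_number))
  for (w in x$diagnostics$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Apply the negativity policy to a decomposition result
#'
#' `clip_zero` (default elsewhere) replaces negative raw components with
#' zero — negative thickness is unphysical; `keep_raw` passes the raw solver
#' output through for diagnostic use.
#'
#' @param result A `decomposition_result`.
#' @param policy `"clip_zero"` or `"keep_raw"`.
#' @return A [thickness_maps()].
#' @export
postprocess <- function(result, policy = c("clip_zero", "keep_raw")) {
  stopifnot(inherits(result, "decomposition_result"))
  policy <- match.arg(policy)
  maps <- result$thickness_maps
  if (policy == "keep_raw") {
    out <- maps
    out$values <- maps$raw_values
    return(out)
  }
  maps
}

#' Render a thickness map as an inverse-video grayscale image
#'
#' Thickness is drawn as darkness: 0 cm maps to white (full scale), values
#' at or above `display_max` map to black. No-data pixels render at a
#' mid-gray sentinel. Gray levels are quantized with round-half-away-from-
#' zero.
#'
#' @param map 2-D numeric thickness matrix (cm), `NA` for no-data.
#' @param display_max Thickness (cm) rendered as black; defaults to the
#'   99th percentile of the finite map values.
#' @param bit_depth Output bit depth, default 8.
#' @return An [intensity_image()] (no wavelength).
#' @export
render_thickness_image <- function(map, display_max = NULL, bit_depth = 8L) {
  stopifnot(is.matrix(map))
  if (is.null(display_max))
    display_max <- stats::quantile(map[is.finite(map)], 0.99, names = FALSE)
  if (!is.finite(display_max) || display_max <= 0)
    stop("display_max must be positive")
  full <- 2^bit_depth - 1
  frac <- pmin(pmax(map / display_max, 0), 1)
  gray <- round_half_away((1 - frac) * full)
  gray[!is.finite(map)] <- round_half_away(full / 2)
  intensity_image(gray, bit_depth = bit_depth)
}
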