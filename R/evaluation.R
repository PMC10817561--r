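#' Binary tissue segmentation mask
#'
#' @param pixels Logical matrix, `TRUE` inside the tissue's area.
#' @param tissue_label Tissue name.
#' @param source `"ground_truth"` or `"decomposed"`.
#' @return An object of class `segmentation_mask`.
#' @export
segmentation_mask <- function(pixels, tissue_label,
                              source = c("decomposed", "ground_truth")) {
  stopifnot(is.matrix(pixels), is.logical(pixels))
  structure(list(pixels = pixels, tissue_label = tissue_label,
                 source = match.arg(source)),
            class = "segmentation_mask")
}

#' Threshold a thickness map into a segmentation mask
#'
#' Reproducible surrogate for manual boundary marking: pixels above a
#' threshold belong to the tissue. `"otsu"` (default) picks the threshold
#' maximizing between-class variance on a 256-bin histogram of the finite
#' values; `"fixed"` uses `fixed_value`. `NA` (no-data) pixels are always
#' outside the mask.
#'
#' @param map 2-D numeric thickness matrix (cm).
#' @param method `"otsu"` or `"fixed"`.
#' @param fixed_value Threshold in cm for `method = "fixed"`.
#' @param tissue_label,source Stored in the returned mask.
#' @return A [segmentation_mask()] with the threshold in attribute
#'   `"threshold"`.
#' @export
threshold_mask <- function(map, method = c("otsu", "fixed"), fixed_value = NULL,
                           tissue_label = "", source = "decomposed") {
  stopifnot(is.matrix(map))
  method <- match.arg(method)
  v <- map[is.finite(map)]
  thr <- if (method == "fixed") {
    if (is.null(fixed_value)) stop("fixed_value required for method = 'fixed'")
    fixed_value
  } else {
    if (length(unique(v)) < 2L)
      stop("map is constant; otsu thresholding is undefined - use method = 'fixed'")
    otsu_threshold(v)
  }
  px <- !is.na(map) & map > thr
  out <- segmentation_mask(px, tissue_label, source)
  attr(out, "threshold") <- thr
  out
}

# Otsu's method on a 256-bin histogram: threshold (bin midpoint between
# classes) maximizing between-class variance.
otsu_threshold <- function(v, n_bins = 256L) {
  rng <- range(v)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(v, edges, rightmost.closed = TRUE), nbins = n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- (edges[-1] + edges[-(n_bins + 1L)]) / 2
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  denom <- omega * (1 - omega)
  sigma_b2 <- ifelse(denom > 0, (mu_t * omega - mu)^2 / denom, -Inf)
  sigma_b2 <- sigma_b2[-n_bins]  # threshold must split the range
  # ties (flat variance across an empty gap between modes) break to the
  # middle of the plateau
  best <- which(sigma_b2 > max(sigma_b2) - 1e-12 * abs(max(sigma_b2)))
  mean(edges[best + 1L])
}

#' Matching-area overlap ratio
#'
#' The asymmetric accuracy measure `|pred intersect ref| / |ref|`: the
#' fraction of the reference tissue area recovered by the prediction. Equals
#' 1 whenever the reference is contained in the prediction.
#'
#' @param pred,ref [segmentation_mask()]s of one frame; `ref` must be
#'   nonempty.
#' @return Scalar in `[0, 1]`.
#' @export
overlap_ratio <- function(pred, ref) {
  p <- mask_pixels(pred); r <- mask_pixels(ref)
  if (!identical(dim(p), dim(r))) stop("mask shapes differ")
  n_ref <- sum(r)
  if (n_ref == 0L) stop("reference mask is empty")
  sum(p & r) / n_ref
}

#' Sorensen-Dice similarity coefficient
#'
#' Symmetric overlap `2 |A intersect B| / (|A| + |B|)`; two empty masks
#' compare as 1 by convention.
#'
#' @param pred,ref [segmentation_mask()]s of one frame.
#' @return Scalar in `[0, 1]`.
#' @export
dice <- function(pred, ref) {
  p <- mask_pixels(pred); r <- mask_pixels(ref)
  if (!identical(dim(p), dim(r))) stop("mask shapes differ")
  denom <- sum(p) + sum(r)
  if (denom == 0L) return(1)
  2 * sum(p & r) / denom
}

mask_pixels <- function(m) {
  if (inherits(m, "segmentation_mask")) m$pixels
  else if (is.matrix(m) && is.logical(m)) m
  else stop("expected a segmentation_mask or logical matrix")
}

#' Continuous recovery metrics against ground truth
#'
#' Per-tissue root-mean-square error, maximum absolute error and bias (mean
#' signed error) of recovered thickness maps over the valid mask, in cm.
#'
#' @param pred,truth [thickness_maps()] with identical shape and tissue
#'   order.
#' @return Data frame with one row per tissue: `tissue`, `rmse_cm`,
#'   `max_abs_err_cm`, `bias_cm`.
#' @export
recovery_metrics <- function(pred, truth) {
  stopifnot(inherits(pred, "thickness_maps"), inherits(truth, "thickness_maps"))
  if (!identical(pred$tissue_labels, truth$tissue_labels))
    stop("tissue label order mismatch: (",
         paste(pred$tissue_labels, collapse = ", "), ") vs (",
         paste(truth$tissue_labels, collapse = ", "), ")")
  if (!identical(dim(pred$values), dim(truth$values)))
    stop("shape mismatch between prediction and truth")
  valid <- pred$valid_mask & truth$valid_mask
  rows <- lapply(seq_along(pred$tissue_labels), function(j) {
    e <- (pred$values[, , j] - truth$values[, , j])[valid]
    e <- e[is.finite(e)]
    data.frame(tissue = pred$tissue_labels[j],
               rmse_cm = sqrt(mean(e^2)),
               max_abs_err_cm = max(abs(e)),
               bias_cm = mean(e))
  })
  do.call(rbind, rows)
}

#' Full accuracy report of a decomposition against ground truth
#'
#' For each tissue: segmentation masks from the predicted and ground-truth
#' maps (Otsu by default, automatically falling back to a small fixed
#' threshold on constant maps), their matching-area overlap ratio and
#' Sorensen-Dice coefficient, areas in pixels, and the continuous recovery
#' metrics. The overlap ratio and the Dice coefficient are reported side by
#' side as distinct quantities.
#'
#' @param pred,truth [thickness_maps()] of one frame, same tissue order.
#' @param method,fixed_value Passed to [threshold_mask()]; the ground-truth
#'   map of each tissue uses the same method.
#' @return An `accuracy_report` data frame, one row per tissue, with columns
#'   `tissue, overlap_ratio, dice, area_pred, area_ref, rmse_cm,
#'   max_abs_err_cm, bias_cm`.
#' @export
accuracy_report <- function(pred, truth, method = "otsu", fixed_value = NULL) {
  metrics <- recovery_metrics(pred, truth)
  rows <- lapply(seq_along(pred$tissue_labels), function(j) {
    lab <- pred$tissue_labels[j]
    mk <- function(map, src) {
      tryCatch(threshold_mask(map, method = method, fixed_value = fixed_value,
                              tissue_label = lab, source = src),
               error = function(e)
                 threshold_mask(map, method = "fixed", fixed_value = 1e-9,
                                tissue_label = lab, source = src))
    }
    pm <- mk(pred$values[, , j], "decomposed")
    rm_ <- mk(truth$values[, , j], "ground_truth")
    data.frame(tissue = lab,
               overlap_ratio = if (sum(rm_$pixels) > 0) overlap_ratio(pm, rm_)
                               else NA_real_,
               dice = dice(pm, rm_),
               area_pred = sum(pm$pixels), area_ref = sum(rm_$pixels))
  })
  out <- merge(do.call(rbind, rows), metrics, by = "tissue", sort = FALSE)
  class(out) <- c("accuracy_report", "data.frame")
  out
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat("Decomposition accuracy (per tissue):\n")
  cat(sprintf("%-10s %14s %8s %12s %12s %10s\n",
              "tissue", "overlap_ratio", "dice", "area_pred", "area_ref",
              "rmse_cm"))
  for (i in seq_len(nrow(x)))
    cat(sprintf("%-10s %13.1f%% %7.1f%% %12d %12d %10.4g\n",
                x$tissue[i], 100 * x$overlap_ratio[i], 100 * x$dice[i],
                x$area_pred[i], x$area_ref[i], x$rmse_cm[i]))
  invisible(x)
}
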