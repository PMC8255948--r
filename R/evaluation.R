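# Evaluation metrics: image mean squared error in dB, and ensemble
# bias / standard deviation over independent noise realizations, both
# for ROI means and pixel-wise.

#' Image mean squared error in dB
#'
#' `10 log10(||est - truth||^2 / ||truth||^2)`, with Euclidean norms
#' over all pixels. An estimate identical to the truth has no finite
#' MSE; `-Inf` is returned with a warning as the perfect-reconstruction
#' sentinel.
#'
#' @param est,truth Images (matrices) on the same grid.
#' @return Scalar MSE in dB (more negative is better).
#' @export
mse_db <- function(est, truth) {
  if (!all(dim(est) == dim(truth))) stop("images must share the same grid")
  den <- sum(truth^2)
  if (den == 0) stop("truth image has zero norm")
  num <- sum((est - truth)^2)
  if (num == 0) {
    warning("estimate is identical to the truth (perfect reconstruction)")
    return(-Inf)
  }
  10 * log10(num / den)
}

#' Ensemble set of reconstructions
#'
#' Bundles reconstructions of the same object from independent noise
#' realizations with the matching ground truth.
#'
#' @param images List of images (matrices), one per realization.
#' @param truth Ground-truth image on the same grid.
#' @return An `ensemble_set`.
#' @export
ensemble_set <- function(images, truth) {
  if (length(images) < 1L) stop("at least one realization is required")
  for (im in images)
    if (!all(dim(im) == dim(truth))) stop("all images must share one grid")
  structure(list(images = images, truth = truth, n_r = length(images)),
            class = "ensemble_set")
}

#' ROI ensemble bias and standard deviation
#'
#' With `c_i` the ROI mean of realization i, `c_true` the ROI mean of
#' the truth and `cbar` the ensemble mean:
#' `bias = |cbar - c_true| / c_true` and
#' `sd = sqrt(sum((c_i - cbar)^2) / (N_r - 1)) / c_true`
#' (both unitless proportions).
#'
#' @param ens An [ensemble_set()].
#' @param roi Logical mask (matrix), nonempty, with positive true mean.
#' @return Named vector `c(bias, sd)`; `sd` is `NA` for a single
#'   realization.
#' @export
roi_bias_sd <- function(ens, roi) {
  stopifnot(inherits(ens, "ensemble_set"))
  if (!any(roi)) stop("ROI is empty")
  c_true <- mean(ens$truth[roi])
  if (c_true <= 0) stop("ROI true mean must be positive")
  ci <- vapply(ens$images, function(im) mean(im[roi]), 0)
  cbar <- mean(ci)
  sd <- if (ens$n_r >= 2) sqrt(sum((ci - cbar)^2) / (ens$n_r - 1)) / c_true
        else NA_real_
  c(bias = abs(cbar - c_true) / c_true, sd = sd)
}

#' Pixel-based ensemble bias and standard deviation (percent)
#'
#' Applies the ROI formula per pixel (normalizing by the pixel's true
#' value) and averages over the region, in percent. Region pixels with
#' nonpositive truth are excluded with a warning.
#'
#' @param ens An [ensemble_set()].
#' @param region Logical mask (matrix).
#' @return Named vector `c(bias, sd)` in percent.
#' @export
pixel_bias_sd <- function(ens, region) {
  stopifnot(inherits(ens, "ensemble_set"))
  if (!any(region)) stop("region is empty")
  keep <- region & ens$truth > 0
  if (sum(keep) < sum(region))
    warning(sum(region) - sum(keep),
            " region pixel(s) with nonpositive truth excluded")
  if (!any(keep)) stop("no region pixels with positive truth")
  truth <- ens$truth[keep]
  vals <- vapply(ens$images, function(im) im[keep], truth)
  vals <- matrix(vals, nrow = sum(keep))
  cbar <- rowMeans(vals)
  bias <- mean(abs(cbar - truth) / truth) * 100
  sd <- if (ens$n_r >= 2) {
    sdp <- sqrt(rowSums((vals - cbar)^2) / (ens$n_r - 1)) / truth
    mean(sdp) * 100
  } else NA_real_
  c(bias = bias, sd = sd)
}
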