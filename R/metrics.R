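#' Air-excluded percentage error between projection images
#'
#' Per-pixel `100 * |predicted - reference| / reference` over pixels
#' whose reference line integral exceeds `air_threshold`; pixels at or
#' below the threshold represent air trajectories (or near-zero
#' references that would inflate the ratio) and are excluded from the
#' statistics.
#'
#' @param predicted,reference Numeric arrays of identical shape (single
#'   images or stacks).
#' @param air_threshold Reference value at or below which a pixel counts
#'   as air (line-integral units). Default 0.01.
#' @return A `monoct_errorsummary`: list with `mean_pct`, `sd_pct`,
#'   `error_map` (NA where excluded), `excluded` mask and `n_excluded`.
#' @export
percentage_error <- function(predicted, reference, air_threshold = 0.01) {
  if (!identical(dim(predicted), dim(reference))) {
    stop("shape mismatch between predicted and reference")
  }
  stopifnot(air_threshold >= 0)
  keep <- reference > air_threshold
  if (!any(keep)) stop("all pixels excluded as air trajectories")
  err <- array(NA_real_, dim(predicted))
  err[keep] <- 100 * abs(predicted[keep] - reference[keep]) / reference[keep]
  structure(list(mean_pct = mean(err[keep]),
                 sd_pct = stats::sd(err[keep]),
                 error_map = err,
                 excluded = !keep,
                 n_excluded = sum(!keep)),
            class = "monoct_errorsummary")
}

#' @export
print.monoct_errorsummary <- function(x, ...) {
  cat(sprintf("percentage error %.2f +/- %.2f %% (%d air pixels excluded)\n",
              x$mean_pct, x$sd_pct, x$n_excluded))
  invisible(x)
}

#' Mean absolute error over all pixels
#'
#' Matches the training loss definition: no air exclusion.
#'
#' @param predicted,reference Numeric arrays of identical shape.
#' @return Scalar MAE in line-integral units.
#' @export
mae <- function(predicted, reference) {
  if (!identical(dim(predicted), dim(reference))) {
    stop("shape mismatch between predicted and reference")
  }
  mean(abs(predicted - reference))
}

#' Uniformity metric (UNAAD) of a region of interest
#'
#' `UNAAD = 100 - 100 / (N * mean(Y)) * sum(|Y_i - mean(Y)|)` over the
#' ROI voxels: 100 for a perfectly constant region, lower for less
#' uniform ones, invariant under positive scaling of the values.
#'
#' @param volume A `monoct_volume` or numeric array.
#' @param roi Logical mask of the same shape (default: all voxels).
#' @return UNAAD value in `(-Inf, 100]`.
#' @export
unaad <- function(volume, roi = NULL) {
  v <- if (inherits(volume, "monoct_volume")) volume$values else volume
  if (is.null(roi)) roi <- array(TRUE, dim(v))
  if (!identical(dim(roi), dim(v))) stop("ROI mask shape mismatch")
  y <- v[roi]
  if (length(y) == 0) stop("empty ROI")
  ybar <- mean(y)
  if (ybar == 0) stop("ROI mean is zero; UNAAD undefined")
  100 - 100 / (length(y) * ybar) * sum(abs(y - ybar))
}

#' Percentage difference map between two reconstructions
#'
#' Per-voxel `100 * (raw - corrected) / corrected` inside a body mask
#' (voxels where `|corrected|` exceeds `threshold`); visualization/QA of
#' where beam hardening moved the reconstructed values.
#'
#' @param raw,corrected `monoct_volume`s on the same grid.
#' @param threshold Body-mask threshold on `|corrected|` (1/cm).
#' @return List with `map` (NA outside the mask), `mask`, and masked
#'   summary statistics `mean_pct`, `max_abs_pct`.
#' @export
reconstruction_difference_map <- function(raw, corrected, threshold = 0.05) {
  stopifnot(inherits(raw, "monoct_volume"), inherits(corrected, "monoct_volume"))
  if (!identical(dim(raw$values), dim(corrected$values))) {
    stop("volume grids differ")
  }
  mask <- abs(corrected$values) > threshold
  map <- array(NA_real_, dim(raw$values))
  map[mask] <- 100 * (raw$values[mask] - corrected$values[mask]) /
    corrected$values[mask]
  list(map = map, mask = mask,
       mean_pct = mean(map[mask]),
       max_abs_pct = if (any(mask)) max(abs(map[mask])) else NA_real_)
}

#' Paired comparison of prediction errors between two pixel groups
#'
#' Convenience wrapper around the stock Wilcoxon signed-rank test,
#' e.g. to compare prediction losses on long versus short beam paths.
#'
#' @param errors_a,errors_b Paired error samples.
#' @return The `htest` object from [stats::wilcox.test()].
#' @export
compare_path_errors <- function(errors_a, errors_b) {
  stats::wilcox.test(errors_a, errors_b, paired = TRUE)
}
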