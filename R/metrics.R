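# Region-of-interest electric-field statistics and montage-comparison
# metrics.

#' ROI electric-field statistics
#'
#' Unweighted statistics over the field-magnitude values of the ROI voxels
#' (voxels have uniform volume, so no weighting is needed): mean, population
#' standard deviation, and the 99th percentile, which the GVS literature
#' reports as the "max" to suppress numerical hot-spots. The percentile uses
#' linear interpolation between order statistics.
#'
#' @param efield An `efield_volume` from [compute_efield()].
#' @param roi Logical mask array, or integer label ids when `vol` is given.
#' @param vol Optional `tissue_label_volume` for label-based ROIs.
#' @return A list of class `"roi_metrics"`: `mean_V_per_m`, `sd_V_per_m`,
#'   `p99_V_per_m`, `n_voxels` (and `current_uA = NA`, fill via
#'   [roi_inflow_current()]).
#' @export
roi_statistics <- function(efield, roi, vol = NULL) {
  if (!is.logical(roi)) {
    if (is.null(vol)) stop("label-based ROIs need `vol`")
    roi <- roi_mask(vol, roi)
  }
  vals <- efield$Emag[roi]
  vals <- vals[!is.na(vals)]
  if (!length(vals)) stop("empty ROI")
  n <- length(vals)
  structure(list(
    mean_V_per_m = mean(vals),
    sd_V_per_m = sqrt(sum((vals - mean(vals))^2) / n),
    p99_V_per_m = unname(quantile(vals, 0.99, type = 7)),
    n_voxels = n,
    current_uA = NA_real_
  ), class = "roi_metrics")
}

#' @export
print.roi_metrics <- function(x, ...) {
  cat("<roi_metrics> mean ", signif(x$mean_V_per_m, 4), " V/m, sd ",
      signif(x$sd_V_per_m, 4), ", p99 ", signif(x$p99_V_per_m, 4),
      " (", x$n_voxels, " voxels)\n", sep = "")
  invisible(x)
}

#' Left/right symmetricity of induced fields
#'
#' Ratio of left-side over right-side ROI metrics, computed from the mean
#' and from the 99th-percentile ("max") field values. A value of 1 means
#' identical flow in the two vestibular networks.
#'
#' @param left,right `"roi_metrics"` for the two sides (or bare lists with
#'   `mean_V_per_m` and `p99_V_per_m`).
#' @return List of class `"symmetricity_report"` with `mean_ratio` and
#'   `max_ratio`.
#' @examples
#' symmetricity(list(mean_V_per_m = 0.028, p99_V_per_m = 0.147),
#'              list(mean_V_per_m = 0.030, p99_V_per_m = 0.172))
#' @export
symmetricity <- function(left, right) {
  eps <- .Machine$double.eps
  if (!(right$mean_V_per_m > eps) || !(right$p99_V_per_m > eps))
    stop("degenerate denominator: right-side metric is ~0")
  structure(list(
    mean_ratio = left$mean_V_per_m / right$mean_V_per_m,
    max_ratio = left$p99_V_per_m / right$p99_V_per_m
  ), class = "symmetricity_report")
}

#' @export
print.symmetricity_report <- function(x, ...) {
  cat("<symmetricity> mean ratio ", signif(x$mean_ratio, 4),
      ", max ratio ", signif(x$max_ratio, 4), "\n", sep = "")
  invisible(x)
}

#' Scalp current required to match a reference field
#'
#' By linearity of the quasi-static field solution, the injected current
#' needed for a candidate montage to reproduce a reference montage's mean
#' ROI field is `base_current * reference_mean / candidate_mean`.
#'
#' @param reference_mean,candidate_mean Mean ROI field strengths (V/m).
#' @param base_current_mA Current at which `candidate_mean` was obtained.
#' @return Required current in mA.
#' @examples
#' scale_to_match(0.028, 0.013) # ~2.15 mA
#' @export
scale_to_match <- function(reference_mean, candidate_mean, base_current_mA = 1) {
  if (!(candidate_mean > .Machine$double.eps))
    stop("candidate_mean is ~0; cannot rescale")
  base_current_mA * reference_mean / candidate_mean
}

#' Percentile-bootstrap confidence interval for a ROI mean field
#'
#' @param values Numeric sample (ROI voxel field magnitudes), length >= 2.
#' @param level Confidence level in (0, 1).
#' @param n_boot Number of bootstrap resamples.
#' @param seed RNG seed; results are deterministic given the seed and the
#'   caller's RNG state is left untouched.
#' @return Numeric `c(lower, upper)` (V/m) with attribute `level`. A
#'   degenerate all-equal sample gives a zero-width interval.
#' @export
bootstrap_ci <- function(values, level = 0.95, n_boot = 2000, seed = 42) {
  if (length(values) < 2) stop("need at least 2 values")
  if (!(level > 0 && level < 1)) stop("level must be in (0, 1)")
  means <- with_local_seed(seed, {
    n <- length(values)
    vapply(seq_len(n_boot),
           function(i) mean(values[sample.int(n, n, replace = TRUE)]),
           numeric(1))
  })
  alpha <- (1 - level) / 2
  ci <- unname(quantile(means, c(alpha, 1 - alpha), type = 7))
  structure(ci, names = c("lower", "upper"), level = level)
}

#' Normalize a montage-by-category metric table for star plots
#'
#' Divides every value by its category (column) maximum so that each
#' category's best montage maps to 1, enabling overlaid star plots of
#' montages across metrics.
#'
#' @param metric_table Data frame or matrix; non-numeric columns are kept as
#'   identifiers.
#' @return Same shape, numeric columns scaled to `[0, 1]`.
#' @export
starplot_normalize <- function(metric_table) {
  if (is.matrix(metric_table)) {
    mx <- apply(metric_table, 2, max, na.rm = TRUE)
    if (any(!(mx > 0))) stop("every category must have a positive maximum")
    return(sweep(metric_table, 2, mx, "/"))
  }
  for (col in names(metric_table)) {
    if (!is.numeric(metric_table[[col]])) next
    mx <- max(metric_table[[col]], na.rm = TRUE)
    if (!(mx > 0))
      stop("category '", col, "' must have a positive maximum")
    metric_table[[col]] <- metric_table[[col]] / mx
  }
  metric_table
}
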