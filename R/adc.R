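#' ADC calibration constants
#'
#' Fixed constants of the ADC-to-cell-density conversion: the healthy-tissue
#' ADC \code{adc_h} (estimated from a healthy-tissue region of interest), the
#' ratio \code{ratio_min = ADC_min / ADC_h} giving the minimum ADC observable
#' within a tumor (lower asymptote of the GS-ADC sigmoid), and the tumor-core
#' threshold \code{core_ratio} as a fraction of \code{adc_h}.
#'
#' @param adc_h healthy-tissue ADC, same units as the ADC map (> 0).
#' @param ratio_min \code{ADC_min / ADC_h}, dimensionless; default 0.25.
#' @param core_ratio tumor-core threshold as a fraction of \code{adc_h};
#'   default 0.70.
#' @return An object of class \code{"adc_calibration"}.
#' @examples
#' cal <- adc_calibration(adc_h = 1.4)
#' adc_to_density(0.98, cal)   # 70% of adc_h -> 0.4
#' @export
adc_calibration <- function(adc_h = 1, ratio_min = 0.25, core_ratio = 0.70) {
  check_scalar(adc_h, "adc_h", positive = TRUE)
  check_scalar(ratio_min, "ratio_min")
  check_scalar(core_ratio, "core_ratio")
  stop_if(!(ratio_min > 0 && ratio_min < core_ratio && core_ratio < 1),
          "need 0 < ratio_min < core_ratio < 1")
  structure(list(adc_h = adc_h, ratio_min = ratio_min,
                 core_ratio = core_ratio, adc_min = ratio_min * adc_h),
            class = "adc_calibration")
}

#' @export
print.adc_calibration <- function(x, ...) {
  cat(sprintf("adc_calibration: adc_h = %g, adc_min = %g (ratio %.2f), core threshold %.0f%% of adc_h\n",
              x$adc_h, x$adc_min, x$ratio_min, 100 * x$core_ratio))
  invisible(x)
}

#' Estimate healthy-tissue ADC from a reference region
#'
#' Arithmetic mean ADC over a manually delineated healthy-tissue region of
#' interest, used as the patient's \code{adc_h}.
#'
#' @param adc ADC [image_volume()] or 3D array.
#' @param roi logical mask aligned with \code{adc}.
#' @return Scalar mean ADC over the region.
#' @export
estimate_healthy_adc <- function(adc, roi) {
  a <- if (inherits(adc, "image_volume")) adc$data else adc
  roi <- check_mask(roi, "roi")
  stop_if(!same_dim(a, roi), "'adc' and 'roi' grids differ")
  stop_if(!any(roi), "healthy-tissue ROI is empty")
  mean(a[roi])
}

#' Convert ADC to normalized tumor cell density (and back)
#'
#' Maps ADC to normalized tumor cell density via the linear relation
#' \deqn{\bar N = (ADC_h - ADC) / (ADC_h - ADC_{min}),}
#' truncated so that ADC values above \eqn{ADC_h} give 0 and values below
#' \eqn{ADC_{min}} give 1 (cellularity cannot be negative nor exceed the
#' carrying capacity). \code{density_to_adc()} is the exact inverse on
#' \eqn{[0, 1]} and is used by the synthetic-data generator.
#'
#' @param adc ADC values (any numeric shape; units of \code{cal$adc_h}).
#' @param nbar normalized densities in \eqn{[0, 1]}.
#' @param cal an [adc_calibration()].
#' @return Numeric of the same shape: densities in \eqn{[0, 1]}, or ADC
#'   values in \eqn{[ADC_{min}, ADC_h]}.
#' @examples
#' cal <- adc_calibration(adc_h = 1)
#' adc_to_density(c(0.70, 1.1, 0.1), cal)  # 0.4, 0 (truncated), 1 (truncated)
#' @export
adc_to_density <- function(adc, cal) {
  stopifnot(inherits(cal, "adc_calibration"))
  stop_if(!all(is.finite(adc)), "'adc' must be finite")
  nbar <- (cal$adc_h - adc) / (cal$adc_h - cal$adc_min)
  nbar[adc >= cal$adc_h] <- 0
  nbar[adc <= cal$adc_min] <- 1
  nbar
}

#' @rdname adc_to_density
#' @export
density_to_adc <- function(nbar, cal) {
  stopifnot(inherits(cal, "adc_calibration"))
  stop_if(any(nbar < 0 | nbar > 1 | !is.finite(nbar)),
          "'nbar' must lie in [0, 1]")
  cal$adc_h - nbar * (cal$adc_h - cal$adc_min)
}

#' Fit the hyperbolic-tangent GS-ADC model
#'
#' Fits the sigmoidal relation between Gleason score (on a continuous 0-10
#' scale, values 0-2 representing healthy tissue) and the ADC ratio
#' \eqn{ADC/ADC_h}:
#' \deqn{f(GS) = \frac{u + l}{2} - \frac{u - l}{2}\tanh(s\,(GS - m)),}
#' with the upper asymptote pinned at \eqn{u = 1} (healthy tissue) and the
#' lower at \eqn{l = ratio_{min}}; only the steepness \eqn{s} and midpoint
#' \eqn{m} are estimated, by nonlinear least squares.
#'
#' A small synthetic stand-in for the literature (GS, ADC-ratio) means is
#' shipped in \code{system.file("extdata", "gs_adc_literature_synthetic.csv",
#' package = "fkprost")}.
#'
#' @param gs numeric Gleason scores (continuous 0-10 scale), length >= 3.
#' @param adc_ratio observed \eqn{ADC/ADC_h}, same length.
#' @param ratio_min lower asymptote; default 0.25.
#' @param start optional named start values \code{c(slope =, midpoint =)}.
#' @return Object of class \code{"gs_adc_model"}: slope, midpoint, the fixed
#'   asymptotes, and the residual sum of squares. Evaluate it with
#'   \code{predict(model, gs)}.
#' @export
fit_gs_adc_model <- function(gs, adc_ratio, ratio_min = 0.25, start = NULL) {
  stop_if(length(gs) != length(adc_ratio), "'gs' and 'adc_ratio' lengths differ")
  stop_if(length(gs) < 3L, "need at least 3 (GS, ADC ratio) points")
  stop_if(diff(range(gs)) <= 0, "degenerate fit: all GS values equal")
  upper <- 1
  mid <- (upper + ratio_min) / 2
  amp <- (upper - ratio_min) / 2
  if (is.null(start))
    start <- c(slope = 1, midpoint = stats::weighted.mean(
      gs, w = pmax(1e-6, amp^2 - (adc_ratio - mid)^2)))
  df <- data.frame(gs = gs, r = adc_ratio)
  fit <- minpack.lm::nlsLM(
    r ~ mid - amp * tanh(slope * (gs - midpoint)),
    data = df, start = as.list(start),
    lower = c(slope = 1e-6, midpoint = -10), upper = c(slope = 100, midpoint = 20))
  cf <- coef(fit)
  stop_if(cf[["slope"]] <= 0, "fit produced a non-increasing model")
  structure(list(slope = cf[["slope"]], midpoint = cf[["midpoint"]],
                 upper = upper, lower = ratio_min,
                 rss = sum(residuals(fit)^2), n = length(gs)),
            class = "gs_adc_model")
}

#' @export
predict.gs_adc_model <- function(object, newdata = NULL, ...) {
  gs <- if (is.null(newdata)) seq(0, 10, by = 0.1) else
    if (is.list(newdata)) newdata$gs else newdata
  with(object, (upper + lower) / 2 -
         (upper - lower) / 2 * tanh(slope * (gs - midpoint)))
}

#' @export
print.gs_adc_model <- function(x, ...) {
  cat(sprintf("GS-ADC tanh model: slope %.4g /GS, midpoint GS %.4g, asymptotes [%.2f, %.2f], RSS %.3g (n = %d)\n",
              x$slope, x$midpoint, x$lower, x$upper, x$rss, x$n))
  invisible(x)
}

#' Segment the tumor core by ADC thresholding
#'
#' The tumor core is the set of voxels inside the gross tumor segmentation
#' whose ADC is strictly below \code{core_ratio * adc_h} (by default, 70% of
#' the healthy-tissue ADC).
#'
#' @param adc ADC [image_volume()] or 3D array.
#' @param gross logical gross-tumor mask aligned with \code{adc}.
#' @param cal an [adc_calibration()].
#' @return Logical core mask (subset of \code{gross}).
#' @export
segment_tumor_core <- function(adc, gross, cal) {
  a <- if (inherits(adc, "image_volume")) adc$data else adc
  gross <- check_mask(gross, "gross")
  stopifnot(inherits(cal, "adc_calibration"))
  stop_if(!same_dim(a, gross), "'adc' and 'gross' grids differ")
  gross & (a < cal$core_ratio * cal$adc_h)
}

#' Expand a tumor core by a metric margin
#'
#' Morphological dilation of the core mask by a Euclidean ball of radius
#' \code{margin_mm} (voxel-centre distance), clipped to the gross tumor
#' segmentation. This reproduces the margin expansion that carries the final
#' tumor segmentation out to ADC values near healthy levels, giving the
#' density map a smooth rim compatible with the growth model's travelling
#' fronts.
#'
#' @param core logical core mask.
#' @param gross logical gross-tumor mask (same grid); the result never leaves
#'   it.
#' @param margin_mm dilation radius in mm (>= 0).
#' @param spacing isotropic voxel edge, mm.
#' @return Logical mask with \code{core <= result <= gross}.
#' @export
expand_margin <- function(core, gross, margin_mm, spacing) {
  core <- check_mask(core, "core"); gross <- check_mask(gross, "gross")
  stop_if(!same_dim(core, gross), "'core' and 'gross' grids differ")
  stop_if(any(core & !gross), "'core' must be contained in 'gross'")
  check_scalar(spacing, "spacing", positive = TRUE)
  check_scalar(margin_mm, "margin_mm")
  stop_if(margin_mm < 0, "'margin_mm' must be >= 0")
  r <- floor(margin_mm / spacing + 1e-9)
  if (r < 1 || !any(core)) return(core & gross)
  off <- as.matrix(expand.grid(dx = -r:r, dy = -r:r, dz = -r:r))
  off <- off[rowSums(off^2) * spacing^2 <= margin_mm^2 + 1e-9, , drop = FALSE]
  d <- dim(core)
  ai <- which(core, arr.ind = TRUE)
  out <- array(FALSE, d)
  for (m in seq_len(nrow(off))) {
    p <- ai + rep(off[m, ], each = nrow(ai))
    ok <- p[, 1] >= 1 & p[, 1] <= d[1] & p[, 2] >= 1 & p[, 2] <= d[2] &
      p[, 3] >= 1 & p[, 3] <= d[3]
    out[p[ok, , drop = FALSE]] <- TRUE
  }
  out & gross
}

#' Preprocess one ADC scan into a tumor density map
#'
#' Runs the segmentation/conversion chain on a single scan: threshold the
#' tumor core inside the gross segmentation, expand it by a metric margin to
#' the final tumor segmentation, and convert ADC to normalized tumor cell
#' density. The density map is evaluated over the whole prostate (truncation
#' applied wherever the conversion is evaluated); a version restricted to the
#' final tumor segmentation is also returned.
#'
#' @param adc ADC [image_volume()] or 3D array.
#' @param prostate,gross logical prostate and gross-tumor masks.
#' @param cal an [adc_calibration()].
#' @param margin_mm margin expansion radius, mm; default 3 (the study used
#'   2-4 mm).
#' @param spacing isotropic voxel edge, mm.
#' @return List with \code{core}, \code{final} (masks), \code{density}
#'   (over the prostate) and \code{density_tumor} (zero outside the final
#'   segmentation).
#' @export
preprocess_scan <- function(adc, prostate, gross, cal, margin_mm = 3,
                            spacing = 1) {
  a <- if (inherits(adc, "image_volume")) adc$data else adc
  prostate <- check_mask(prostate, "prostate")
  core <- segment_tumor_core(a, gross, cal)
  final <- expand_margin(core, gross, margin_mm, spacing)
  dens <- array(0, dim(a))
  dens[prostate] <- adc_to_density(a[prostate], cal)
  dens_t <- dens
  dens_t[!final] <- 0
  list(core = core, final = final, density = dens, density_tumor = dens_t)
}
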