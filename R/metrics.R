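#' Tumor volume and total tumor cell volume
#'
#' The tumor region \eqn{\Omega_T} is the set of voxels with density
#' \eqn{\bar N \ge \bar N_{th}} (threshold 0.15 throughout the study). The
#' tumor volume \eqn{V_T} is the volume of \eqn{\Omega_T}; the total tumor
#' cell volume \eqn{V_N = \int_{\Omega_T} \bar N\, dx} weights it by
#' cellularity. Both are reported in cc.
#'
#' @param state an [fk_state()] or 3D density array.
#' @param grid an [fk_grid()] (supplies the voxel volume).
#' @param nbar_th tumor-region density threshold; default 0.15.
#' @return Volume in cc.
#' @export
tumor_volume <- function(state, grid, nbar_th = 0.15) {
  nbar <- if (inherits(state, "fk_state")) state$nbar else state
  sum(nbar >= nbar_th) * grid$spacing^3 / 1000
}

#' @rdname tumor_volume
#' @export
total_cell_volume <- function(state, grid, nbar_th = 0.15) {
  nbar <- if (inherits(state, "fk_state")) state$nbar else state
  sum(nbar[nbar >= nbar_th]) * grid$spacing^3 / 1000
}

#' Tumor region mask
#'
#' @inheritParams tumor_volume
#' @return Logical mask of voxels with \eqn{\bar N \ge} \code{nbar_th}.
#' @export
tumor_region <- function(state, nbar_th = 0.15) {
  nbar <- if (inherits(state, "fk_state")) state$nbar else state
  nbar >= nbar_th
}

#' Dice similarity coefficient
#'
#' Overlap between two segmentations, \eqn{2|a \cap b| / (|a| + |b|)}.
#' Defined as 1 when both masks are empty (perfect agreement of absence).
#'
#' @param a,b logical masks on the same grid.
#' @return Dice coefficient in \eqn{[0, 1]}.
#' @export
dice <- function(a, b) {
  a <- check_mask(a, "a"); b <- check_mask(b, "b")
  stop_if(!same_dim(a, b), "mask shapes differ")
  s <- sum(a) + sum(b)
  if (s == 0) return(1)
  2 * sum(a & b) / s
}

# population-moment concordance statistics; pcc may be NaN (flagged upstream)
pcc_ccc <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
  cxy <- mean((x - mx) * (y - my))
  pcc <- if (vx > 0 && vy > 0) cxy / sqrt(vx * vy) else NaN
  ccc <- 2 * cxy / (vx + vy + (mx - my)^2)
  c(pcc = pcc, ccc = ccc)
}

#' Local model-data agreement over the tumor support
#'
#' Voxelwise agreement between measured and simulated density maps over a
#' support region (by default the union of the measured and simulated tumor
#' regions): root mean squared error, Pearson correlation coefficient, and
#' Lin's concordance correlation coefficient
#' \eqn{CCC = 2 s_{xy} / (s_x^2 + s_y^2 + (\mu_x - \mu_y)^2)}.
#'
#' @param meas,model [fk_state()] objects or density arrays on one grid.
#' @param support logical mask of evaluation voxels; if \code{NULL}, the
#'   union of the two tumor regions at \code{nbar_th}.
#' @param nbar_th threshold used to build the default support.
#' @return Named vector \code{c(rmse, pcc, ccc)}. \code{pcc} is \code{NaN}
#'   with a warning if either field is constant over the support.
#' @export
local_agreement <- function(meas, model, support = NULL, nbar_th = 0.15) {
  m <- if (inherits(meas, "fk_state")) meas$nbar else meas
  s <- if (inherits(model, "fk_state")) model$nbar else model
  stop_if(!same_dim(m, s), "field shapes differ")
  if (is.null(support)) support <- (m >= nbar_th) | (s >= nbar_th)
  support <- check_mask(support, "support")
  stop_if(!same_dim(m, support), "'support' shape differs")
  stop_if(!any(support), "empty evaluation support")
  x <- m[support]; y <- s[support]
  cc <- pcc_ccc(x, y)
  if (is.nan(cc[["pcc"]]))
    warning("constant field over the support: PCC undefined (NaN)")
  c(rmse = sqrt(mean((x - y)^2)), cc)
}

#' Cohort-level concordance of scalar metrics
#'
#' Pearson and Lin concordance correlation between patientwise scalar pairs
#' (e.g., measured vs model tumor volume across the cohort).
#'
#' @param x,y numeric vectors of equal length \eqn{\ge 3}.
#' @return Named vector \code{c(pcc, ccc)}.
#' @export
cohort_concordance <- function(x, y) {
  stop_if(length(x) != length(y), "lengths differ")
  stop_if(length(x) < 3L, "need at least 3 pairs")
  pcc_ccc(as.numeric(x), as.numeric(y))
}

#' Per-scan agreement report
#'
#' One row of the global/local agreement panel comparing a measured and a
#' simulated density state: measured and model \eqn{V_T} and \eqn{V_N},
#' Dice overlap of the tumor regions, and local RMSE/PCC/CCC over their
#' union.
#'
#' @param meas,model [fk_state()] objects on the grid.
#' @param grid an [fk_grid()].
#' @param nbar_th tumor-region threshold; default 0.15.
#' @return A one-row data frame with columns \code{time_days},
#'   \code{v_t_meas}, \code{v_t_model}, \code{v_n_meas}, \code{v_n_model},
#'   \code{dsc}, \code{rmse}, \code{pcc}, \code{ccc}.
#' @export
agreement_report <- function(meas, model, grid, nbar_th = 0.15) {
  rt_m <- tumor_region(meas, nbar_th)
  rt_s <- tumor_region(model, nbar_th)
  la <- if (any(rt_m | rt_s))
    local_agreement(meas, model, support = rt_m | rt_s)
  else c(rmse = NA_real_, pcc = NA_real_, ccc = NA_real_)
  data.frame(time_days = if (inherits(model, "fk_state")) model$t else NA_real_,
             v_t_meas = tumor_volume(meas, grid, nbar_th),
             v_t_model = tumor_volume(model, grid, nbar_th),
             v_n_meas = total_cell_volume(meas, grid, nbar_th),
             v_n_model = total_cell_volume(model, grid, nbar_th),
             dsc = dice(rt_m, rt_s),
             rmse = la[["rmse"]], pcc = la[["pcc"]], ccc = la[["ccc"]])
}
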