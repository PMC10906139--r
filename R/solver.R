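#' Simulation grid on a masked prostate domain
#'
#' Builds the computational domain for the growth model: the set of voxels in
#' the prostate mask, with the 7-point neighbour table used by the masked
#' finite-volume Laplacian. Fluxes across faces leaving the mask are omitted,
#' which enforces the zero-flux (Neumann) boundary condition on the prostate
#' surface: organ-confined disease, no cells leave the prostate.
#'
#' @param mask logical 3D prostate mask (at least one voxel).
#' @param spacing isotropic voxel edge, mm.
#' @param dt time step in days for the implicit integrator; default 1.
#' @return Object of class \code{"fk_grid"}: the mask, spacing, dt, the
#'   flat indices of mask voxels and the 0-based neighbour table.
#' @export
fk_grid <- function(mask, spacing, dt = 1) {
  mask <- check_mask(mask)
  check_scalar(spacing, "spacing", positive = TRUE)
  check_scalar(dt, "dt", positive = TRUE)
  stop_if(!any(mask), "prostate mask is empty")
  d <- dim(mask)
  idx <- which(mask)
  pos <- array(0L, d)
  pos[idx] <- seq_along(idx)
  ai <- arrayInd(idx, d)
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  nbr <- matrix(-1L, nrow = length(idx), ncol = 6L)
  for (k in 1:6) {
    p <- ai + rep(offs[k, ], each = nrow(ai))
    ok <- p[, 1] >= 1 & p[, 1] <= d[1] & p[, 2] >= 1 & p[, 2] <= d[2] &
      p[, 3] >= 1 & p[, 3] <= d[3]
    flat <- p[ok, 1] + (p[ok, 2] - 1L) * d[1] + (p[ok, 3] - 1L) * d[1] * d[2]
    nbr[ok, k] <- pos[flat] - 1L
  }
  structure(list(mask = mask, spacing = spacing, dt = dt,
                 index = idx, nbr = nbr),
            class = "fk_grid")
}

#' @export
print.fk_grid <- function(x, ...) {
  cat(sprintf("fk_grid: %d domain voxels of %s (%.3g mm spacing, dt = %g d, prostate volume %.2f cc)\n",
              length(x$index), paste(dim(x$mask), collapse = " x "),
              x$spacing, x$dt, prostate_volume(x)))
  invisible(x)
}

#' Growth-model parameters
#'
#' Parameters of the normalized Fisher-Kolmogorov model: tumor cell
#' diffusivity \code{D} (mm^2/day) and net proliferation rate \code{rho}
#' (1/day), constrained to the admissible boxes used for calibration.
#' \code{nbar_th} is the density threshold defining the tumor region for
#' volume metrics and biomarkers.
#'
#' @param D tumor cell diffusivity, mm^2/day, in \code{[1e-6, 10]}.
#' @param rho net proliferation rate, 1/day, in \code{[1e-6, 1]}.
#' @param nbar_th tumor-region density threshold, default 0.15.
#' @return Object of class \code{"growth_params"}.
#' @export
growth_params <- function(D, rho, nbar_th = 0.15) {
  check_scalar(D, "D"); check_scalar(rho, "rho"); check_scalar(nbar_th, "nbar_th")
  stop_if(D < 1e-6 - 1e-15 && D != 0, "D out of the admissible range [1e-6, 10] mm^2/day")
  stop_if(D > 10, "D out of the admissible range [1e-6, 10] mm^2/day")
  stop_if(rho < 1e-6 - 1e-15 && rho != 0, "rho out of the admissible range [1e-6, 1] 1/day")
  stop_if(rho > 1, "rho out of the admissible range [1e-6, 1] 1/day")
  stop_if(nbar_th <= 0 || nbar_th >= 1, "'nbar_th' must lie in (0, 1)")
  structure(list(D = D, rho = rho, nbar_th = nbar_th), class = "growth_params")
}

#' @export
print.growth_params <- function(x, ...) {
  cat(sprintf("growth_params: D = %.4g mm^2/day, rho = %.4g 1/day (nbar_th = %g)\n",
              x$D, x$rho, x$nbar_th))
  invisible(x)
}

#' Density state
#'
#' A normalized tumor cell density field \eqn{\bar N \in [0, 1]} at a given
#' time, zero outside the prostate domain.
#'
#' @param nbar 3D array of densities in \eqn{[0, 1]}.
#' @param t time in days.
#' @return Object of class \code{"fk_state"}.
#' @export
fk_state <- function(nbar, t = 0) {
  stop_if(!is.array(nbar) || length(dim(nbar)) != 3L, "'nbar' must be a 3D array")
  stop_if(any(nbar < 0 | nbar > 1 | !is.finite(nbar)),
          "'nbar' must lie in [0, 1]")
  check_scalar(t, "t")
  structure(list(nbar = nbar, t = t), class = "fk_state")
}

#' @export
print.fk_state <- function(x, ...) {
  cat(sprintf("fk_state at t = %g d: max density %.3f, support %d voxels\n",
              x$t, max(x$nbar), sum(x$nbar > 0)))
  invisible(x)
}

as_state_vector <- function(initial, grid) {
  nbar <- if (inherits(initial, "fk_state")) initial$nbar else initial
  stop_if(!same_dim(nbar, grid$mask), "state and grid dimensions differ")
  stop_if(any(nbar[!grid$mask] != 0), "density must be zero outside the prostate mask")
  nbar[grid$index]
}

solver_control <- function(control = list()) {
  def <- list(newton_tol = 1e-8, newton_max = 25L,
              lin_tol = 1e-12, lin_max = 1000L, clip_tol = 1e-6)
  def[names(control)] <- control
  def
}

#' Simulate Fisher-Kolmogorov growth on the prostate domain
#'
#' Integrates the normalized Fisher-Kolmogorov model
#' \deqn{\partial \bar N/\partial t = \nabla\cdot(D \nabla \bar N)
#'   + \rho\, \bar N (1 - \bar N)}
#' with zero-flux boundary conditions on the masked prostate domain, from the
#' initial density state to each requested output time. Time integration is
#' backward Euler with step \code{grid$dt} (a final partial step lands
#' exactly on each output time); each implicit step is solved by Newton
#' iteration with matrix-free conjugate-gradient linear solves.
#'
#' @param initial an [fk_state()] (or bare 3D density array, with
#'   \code{t0} giving its time).
#' @param grid an [fk_grid()].
#' @param params a [growth_params()].
#' @param times output times in days, sorted, all \code{>=} the initial time.
#' @param t0 initial time when \code{initial} is a bare array; default 0.
#' @param control optional list overriding solver tolerances
#'   (\code{newton_tol} 1e-8 relative, \code{newton_max} 25,
#'   \code{lin_tol} 1e-12 relative, \code{lin_max} 1000).
#' @return A list of [fk_state()] objects, one per output time.
#' @examples
#' mask <- array(TRUE, c(5, 5, 5))
#' g <- fk_grid(mask, spacing = 2)
#' n0 <- array(0.1, c(5, 5, 5))
#' s <- fk_simulate(n0, g, growth_params(1e-3, 2e-3), times = c(10, 20))
#' sapply(s, function(x) max(x$nbar))
#' @export
fk_simulate <- function(initial, grid, params, times, t0 = 0,
                        control = list()) {
  stopifnot(inherits(grid, "fk_grid"), inherits(params, "growth_params"))
  stop_if(!is.numeric(times) || length(times) < 1L || any(!is.finite(times)),
          "'times' must be finite")
  stop_if(is.unsorted(times), "'times' must be sorted increasingly")
  if (inherits(initial, "fk_state")) t0 <- initial$t
  stop_if(times[1] < t0 - 1e-9, "'times' must all be >= the initial time")
  u0 <- as_state_vector(initial, grid)
  ctl <- solver_control(control)
  out <- fk_simulate_cpp(u0, grid$nbr, grid$spacing, params$D, params$rho,
                         grid$dt, t0, times,
                         ctl$newton_tol, as.integer(ctl$newton_max),
                         ctl$lin_tol, as.integer(ctl$lin_max), ctl$clip_tol)
  lapply(seq_along(times), function(j) {
    a <- array(0, dim(grid$mask))
    a[grid$index] <- out[, j]
    fk_state(a, times[j])
  })
}

#' Advance the density by one implicit time step
#'
#' Single backward-Euler step of length \code{grid$dt}; a convenience wrapper
#' around [fk_simulate()].
#'
#' @inheritParams fk_simulate
#' @return An [fk_state()] at \code{t0 + grid$dt}.
#' @export
fk_step <- function(initial, grid, params, t0 = 0, control = list()) {
  if (inherits(initial, "fk_state")) t0 <- initial$t
  fk_simulate(initial, grid, params, times = t0 + grid$dt, t0 = t0,
              control = control)[[1]]
}
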