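#' Longitudinal scan series
#'
#' Ordered per-patient scan data: times in days (relative to the first scan,
#' which supplies the initial condition), normalized tumor cell density maps,
#' and optionally the underlying ADC volumes and masks.
#'
#' @param times scan times in days, increasing; \code{times[1]} is the
#'   reference (usually 0).
#' @param density list of 3D density arrays, one per scan, zero outside the
#'   prostate.
#' @param adc optional list of ADC volumes/arrays.
#' @param prostate optional logical prostate mask (shared across scans).
#' @param gross optional list of gross-tumor masks.
#' @return Object of class \code{"scan_series"}.
#' @export
scan_series <- function(times, density, adc = NULL, prostate = NULL,
                        gross = NULL) {
  stop_if(length(times) < 2L, "need at least 2 scans")
  stop_if(is.unsorted(times, strictly = TRUE), "'times' must be strictly increasing")
  stop_if(length(density) != length(times), "one density map per scan required")
  for (d in density)
    stop_if(!is.array(d) || length(dim(d)) != 3L || any(d < 0 | d > 1),
            "density maps must be 3D arrays in [0, 1]")
  structure(list(times = as.numeric(times), density = density, adc = adc,
                 prostate = prostate, gross = gross),
            class = "scan_series")
}

#' @export
print.scan_series <- function(x, ...) {
  cat(sprintf("scan_series: %d scans at t = %s days\n", length(x$times),
              paste(signif(x$times, 4), collapse = ", ")))
  invisible(x)
}

#' Relative least-squares misfit of the growth model
#'
#' The calibration objective: the model is run from the first scan's density
#' map, and for each later scan \eqn{i} the squared model-measurement
#' difference integrated over the prostate domain \eqn{\Omega} is divided by
#' the integrated squared measurement,
#' \deqn{J(D, \rho) = \sum_{i \ge 2}
#'   \frac{\int_\Omega (\bar N^{mod}(x, t_i) - \bar N^{meas}(x, t_i))^2 dx}
#'        {\int_\Omega (\bar N^{meas}(x, t_i))^2 dx}.}
#'
#' @param params a [growth_params()] (or named vector with D, rho).
#' @param series a [scan_series()].
#' @param grid an [fk_grid()].
#' @param control solver control list (see [fk_simulate()]).
#' @return Scalar misfit \eqn{J \ge 0}.
#' @export
fk_misfit <- function(params, series, grid, control = list()) {
  if (!inherits(params, "growth_params"))
    params <- growth_params(params[["D"]], params[["rho"]])
  sum(fk_residuals(params, series, grid, control)^2)
}

# stacked per-voxel residual vector scaled by the per-scan normalizer,
# so that sum(r^2) equals the misfit J
fk_residuals <- function(params, series, grid, control = list()) {
  stopifnot(inherits(series, "scan_series"), inherits(grid, "fk_grid"))
  ns <- length(series$times)
  meas <- lapply(series$density, function(d) d[grid$index])
  norms <- vapply(meas[-1], function(m) sum(m^2), 0)
  stop_if(any(norms <= 0),
          "degenerate normalization: a measured density map is all zero over the domain")
  sim <- fk_simulate(series$density[[1]], grid, params,
                     times = series$times[-1], t0 = series$times[1],
                     control = control)
  unlist(lapply(seq_len(ns - 1L), function(i) {
    (sim[[i]]$nbar[grid$index] - meas[[i + 1L]]) / sqrt(norms[i])
  }), use.names = FALSE)
}

#' Calibration control settings
#'
#' @param max_iter maximum Gauss-Newton iterations (default 50).
#' @param obj_tol relative objective-change convergence tolerance (1e-6).
#' @param fd_step forward finite-difference step in log-parameter space (1e-3).
#' @param min_step smallest line-search fraction before giving up (1e-4).
#' @param solver solver control list passed to [fk_simulate()].
#' @return List of control settings.
#' @export
fk_control <- function(max_iter = 50L, obj_tol = 1e-6, fd_step = 1e-3,
                       min_step = 1e-4, solver = list()) {
  list(max_iter = as.integer(max_iter), obj_tol = obj_tol, fd_step = fd_step,
       min_step = min_step, solver = solver)
}

#' Calibrate the growth model to a scan series
#'
#' Estimates the patient-specific tumor cell diffusivity \code{D} and net
#' proliferation rate \code{rho} by minimizing the relative least-squares
#' misfit [fk_misfit()] between simulated and measured density maps at the
#' scan times, with the first scan serving as the initial condition (it is
#' never fitted). The optimizer is Gauss-Newton on the stacked scaled
#' residual vector, run in log-parameter coordinates to respect the
#' four-orders-of-magnitude admissible boxes, with a forward-difference
#' Jacobian, projection onto the bounds, and a step-halving line search.
#'
#' @param series a [scan_series()] with \eqn{\ge 2} scans.
#' @param grid an [fk_grid()] built from the patient's prostate mask.
#' @param init initial parameter guess; default \code{D} = 5e-3 mm^2/day,
#'   \code{rho} = 2e-3 1/day.
#' @param bounds list with elements \code{D} and \code{rho}, each
#'   \code{c(lower, upper)}; defaults \code{[1e-6, 10]} mm^2/day and
#'   \code{[1e-6, 1]} 1/day.
#' @param control a [fk_control()] list.
#' @return Object of class \code{"fk_fit"} with components \code{params}
#'   (a [growth_params()]), \code{objective}, \code{iterations},
#'   \code{converged}, and \code{trajectory} (per-iteration data frame).
#'   Supports \code{coef}, \code{print}, \code{summary}, \code{predict},
#'   \code{simulate}, \code{residuals} and \code{plot}.
#' @examples
#' \donttest{
#' sp <- cohort_spec(n_patients = 1, dim = c(24, 24, 24), spacing = 2.5,
#'                   noise_sd = 0, seed = 7)
#' pat <- generate_cohort(sp)[[1]]
#' grid <- fk_grid(pat$series$prostate, sp$spacing)
#' fit <- fk_fit(pat$series, grid)
#' coef(fit); pat$true_params
#' }
#' @export
fk_fit <- function(series, grid,
                   init = c(D = 5e-3, rho = 2e-3),
                   bounds = list(D = c(1e-6, 10), rho = c(1e-6, 1)),
                   control = fk_control()) {
  stopifnot(inherits(series, "scan_series"), inherits(grid, "fk_grid"))
  lo <- log(c(bounds$D[1], bounds$rho[1]))
  hi <- log(c(bounds$D[2], bounds$rho[2]))
  z <- pmin(pmax(log(c(init[["D"]], init[["rho"]])), lo), hi)
  blo <- c(bounds$D[1], bounds$rho[1]); bhi <- c(bounds$D[2], bounds$rho[2])
  resid_at <- function(z) {
    p <- pmin(pmax(exp(z), blo), bhi)  # guard log/exp roundoff at the box edge
    fk_residuals(growth_params(p[1], p[2]), series, grid, control$solver)
  }
  r <- resid_at(z)
  J <- sum(r^2)
  traj <- data.frame(iter = 0L, D = exp(z[1]), rho = exp(z[2]), objective = J)
  converged <- FALSE
  it <- 0L
  while (it < control$max_iter) {
    it <- it + 1L
    # forward-difference Jacobian in log-parameters (step inward at the box edge)
    Jac <- vapply(1:2, function(k) {
      hk <- if (z[k] + control$fd_step <= hi[k]) control$fd_step else -control$fd_step
      zk <- z; zk[k] <- zk[k] + hk
      (resid_at(zk) - r) / hk
    }, numeric(length(r)))
    A <- crossprod(Jac)
    g <- crossprod(Jac, r)
    A <- A + diag(1e-12 * max(diag(A), 1), 2)
    dz <- tryCatch(-solve(A, g), error = function(e) -g / max(diag(A)))
    step <- 1
    accepted <- FALSE
    while (step >= control$min_step) {
      zc <- pmin(pmax(z + step * dz, lo), hi)
      rc <- resid_at(zc)
      Jc <- sum(rc^2)
      if (Jc < J) {
        z <- zc; r <- rc
        rel <- (J - Jc) / max(J, 1e-300)
        J <- Jc
        accepted <- TRUE
        traj <- rbind(traj, data.frame(iter = it, D = exp(z[1]),
                                       rho = exp(z[2]), objective = J))
        if (rel < control$obj_tol) converged <- TRUE
        break
      }
      step <- step / 2
    }
    if (!accepted) { converged <- TRUE; break }  # no descent direction left
    if (converged) break
  }
  p <- pmin(pmax(exp(z), blo), bhi)
  structure(list(params = growth_params(p[1], p[2]),
                 objective = J, iterations = it, converged = converged,
                 trajectory = traj, series = series, grid = grid,
                 init = init, bounds = bounds, control = control),
            class = "fk_fit")
}

#' @export
coef.fk_fit <- function(object, ...) {
  c(D = object$params$D, rho = object$params$rho)
}

#' @export
print.fk_fit <- function(x, ...) {
  cat("Fisher-Kolmogorov growth model fit\n")
  cat(sprintf("  scans fitted : %d (initial condition from scan 1)\n",
              length(x$series$times)))
  cat(sprintf("  D            : %.4g mm^2/day\n", x$params$D))
  cat(sprintf("  rho          : %.4g 1/day\n", x$params$rho))
  cat(sprintf("  misfit       : %.4g after %d Gauss-Newton iterations (%s)\n",
              x$objective, x$iterations,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' @export
summary.fk_fit <- function(object, nbar_th = 0.15, ...) {
  rows <- lapply(seq_along(object$series$times)[-1], function(i) {
    st <- fk_simulate(object$series$density[[1]], object$grid, object$params,
                      times = object$series$times[i],
                      t0 = object$series$times[1],
                      control = object$control$solver)[[1]]
    agreement_report(fk_state(object$series$density[[i]],
                              object$series$times[i]),
                     st, object$grid, nbar_th = nbar_th)
  })
  out <- list(fit = object, agreement = do.call(rbind, rows))
  class(out) <- "summary.fk_fit"
  out
}

#' @export
print.summary.fk_fit <- function(x, ...) {
  print(x$fit)
  cat("\nPer-scan model-data agreement:\n")
  print(format(x$agreement, digits = 4), row.names = FALSE)
  invisible(x)
}

#' @export
predict.fk_fit <- function(object, times = NULL, ...) {
  if (is.null(times)) times <- object$series$times[-1]
  fk_simulate(object$series$density[[1]], object$grid, object$params,
              times = times, t0 = object$series$times[1],
              control = object$control$solver)
}

#' @export
simulate.fk_fit <- function(object, nsim = 1, seed = NULL, times = NULL, ...) {
  predict(object, times = times, ...)
}

#' @export
residuals.fk_fit <- function(object, ...) {
  r <- fk_residuals(object$params, object$series, object$grid,
                    object$control$solver)
  attr(r, "scan") <- rep(seq_along(object$series$times)[-1],
                         each = length(object$grid$index))
  r
}

#' @export
plot.fk_fit <- function(x, ...) {
  op <- par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  plot(x$trajectory$iter, x$trajectory$objective, type = "b", log = "y",
       xlab = "Gauss-Newton iteration", ylab = "misfit J", ...)
  title("Calibration trajectory")
  last <- length(x$series$times)
  st <- predict(x, times = x$series$times[last])[[1]]
  mid <- which.max(apply(st$nbar, 3, max))
  image(st$nbar[, , mid], col = gray.colors(64, 0, 1), axes = FALSE,
        main = sprintf("model density, t = %g d (slice %d)",
                       st$t, mid))
  invisible(x)
}

#' Log-spaced grid-search calibration oracle
#'
#' Exhaustive misfit evaluation over an \code{n x n} log-spaced grid of
#' \code{(D, rho)} values inside the bounds. Intended as a brute-force
#' cross-check of [fk_fit()] on small problems.
#'
#' @inheritParams fk_fit
#' @param n grid points per parameter (default 20).
#' @return List with the best \code{params}, its \code{objective}, and the
#'   full misfit \code{surface} (data frame D, rho, objective).
#' @export
fk_grid_search <- function(series, grid, n = 20,
                           bounds = list(D = c(1e-6, 10), rho = c(1e-6, 1)),
                           control = fk_control()) {
  Ds <- pmin(pmax(exp(seq(log(bounds$D[1]), log(bounds$D[2]), length.out = n)),
                  bounds$D[1]), bounds$D[2])
  rhos <- pmin(pmax(exp(seq(log(bounds$rho[1]), log(bounds$rho[2]),
                            length.out = n)), bounds$rho[1]), bounds$rho[2])
  surf <- expand.grid(D = Ds, rho = rhos)
  surf$objective <- vapply(seq_len(nrow(surf)), function(i) {
    fk_misfit(growth_params(surf$D[i], surf$rho[i]), series, grid,
              control$solver)
  }, 0)
  best <- which.min(surf$objective)
  list(params = growth_params(surf$D[best], surf$rho[best]),
       objective = surf$objective[best], surface = surf)
}
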