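#' Synthetic cohort specification
#'
#' Study conditions for the synthetic active-surveillance cohort. Defaults
#' mirror the imaging study the pipeline emulates: prostate volumes spanning
#' 18.5-67.3 cc, calibrated diffusivities and proliferation rates
#' (log-uniform over 5.35e-4 to 5.35e-3 mm^2/day and 7.8e-4 to 5.2e-3 1/day),
#' three scans per patient with interscan gaps of 0.5-2.6 years, ADC stored
#' as the ratio to healthy-tissue ADC (so \code{adc_h = 1}), and additive
#' Gaussian ADC-ratio noise of sd 0.02 truncated to (0, 1.2].
#'
#' @param n_patients cohort size; default 10.
#' @param dim grid dimensions; default \code{c(48, 48, 48)}.
#' @param spacing isotropic voxel edge, mm; default 1.5.
#' @param dt solver time step, days.
#' @param prostate_volume_range prostate volumes, cc.
#' @param D_range,rho_range true-parameter ranges (sampled log-uniformly).
#' @param gap_range_years interscan interval range, years.
#' @param n_scans scans per patient (3, as in the study design).
#' @param tumor_radius_range initial tumor radius range, mm.
#' @param tumor_peak_range initial peak normalized density range.
#' @param noise_sd additive Gaussian noise sd on the ADC ratio; 0 disables.
#' @param ap_cutoff proliferation-activity cutoff (1/day) above which a
#'   patient's final-scan tumor is labelled higher-risk (GS >= 3+4),
#'   giving the classifier stage a ground-truth signal; default 4e-4.
#' @param nbar_th tumor-region threshold.
#' @param seed RNG seed; a fixed seed makes the cohort bit-reproducible.
#' @return List of class \code{"cohort_spec"}.
#' @export
cohort_spec <- function(n_patients = 10, dim = c(48, 48, 48), spacing = 1.5,
                        dt = 1,
                        prostate_volume_range = c(18.5, 67.3),
                        D_range = c(5.35e-4, 5.35e-3),
                        rho_range = c(7.8e-4, 5.2e-3),
                        gap_range_years = c(0.5, 2.6),
                        n_scans = 3,
                        tumor_radius_range = c(3, 6),
                        tumor_peak_range = c(0.6, 0.9),
                        noise_sd = 0.02,
                        ap_cutoff = 4e-4,
                        nbar_th = 0.15,
                        seed = 1L) {
  stop_if(n_scans < 2, "need at least 2 scans per patient")
  rngs <- list(prostate_volume_range, D_range, rho_range, gap_range_years,
               tumor_radius_range, tumor_peak_range)
  for (r in rngs)
    stop_if(length(r) != 2L || any(r <= 0) || r[2] < r[1],
            "ranges must be positive and increasing")
  structure(list(n_patients = as.integer(n_patients), dim = as.integer(dim),
                 spacing = spacing, dt = dt,
                 prostate_volume_range = prostate_volume_range,
                 D_range = D_range, rho_range = rho_range,
                 gap_range_years = gap_range_years,
                 n_scans = as.integer(n_scans),
                 tumor_radius_range = tumor_radius_range,
                 tumor_peak_range = tumor_peak_range,
                 noise_sd = noise_sd, ap_cutoff = ap_cutoff,
                 nbar_th = nbar_th, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Ellipsoidal prostate mask of a requested volume
#'
#' Voxelizes an ellipsoid of volume \code{volume_cc} centred in the grid,
#' with fixed semi-axis ratios 1.25 : 1 : 0.85 (prostates are wider than
#' tall). The voxelized volume is within 2\% of the request at the default
#' resolution.
#'
#' @param volume_cc target volume in cc.
#' @param dim grid dimensions (length 3).
#' @param spacing isotropic voxel edge, mm.
#' @return Logical 3D mask.
#' @export
make_prostate <- function(volume_cc, dim, spacing) {
  check_scalar(volume_cc, "volume_cc", positive = TRUE)
  ratios <- c(1.25, 1, 0.85)
  s <- (3 * volume_cc * 1000 / (4 * pi * prod(ratios)))^(1 / 3)
  ax <- ratios * s
  stop_if(any(2 * ax > (dim - 2) * spacing),
          "requested prostate volume does not fit in the grid")
  ctr <- (dim + 1) / 2
  co <- lapply(1:3, function(k) ((seq_len(dim[k]) - ctr[k]) * spacing / ax[k])^2)
  q <- outer(outer(co[[1]], co[[2]], "+"), co[[3]], "+")
  mask <- array(q <= 1, dim)
  stop_if(!any(mask), "requested prostate volume smaller than one voxel")
  mask
}

#' Seed a focal tumor inside the prostate
#'
#' Smooth radial initial condition: a truncated Gaussian profile of peak
#' density \code{peak_nbar} and support radius \code{radius_mm} (the profile
#' reaches 0 continuously at the support edge), clipped to the prostate.
#'
#' @param prostate logical prostate mask.
#' @param center voxel index (length 3) of the tumor centre; must lie inside
#'   the prostate.
#' @param radius_mm support radius, mm.
#' @param peak_nbar peak normalized density in (0, 1].
#' @param spacing isotropic voxel edge, mm.
#' @return An [fk_state()] at t = 0.
#' @export
seed_tumor <- function(prostate, center, radius_mm, peak_nbar, spacing) {
  prostate <- check_mask(prostate, "prostate")
  stop_if(length(center) != 3L, "'center' must be a voxel index triple")
  center <- as.integer(round(center))
  d <- dim(prostate)
  stop_if(any(center < 1L | center > d), "'center' outside the grid")
  stop_if(!prostate[center[1], center[2], center[3]],
          "tumor centre must lie inside the prostate")
  stop_if(peak_nbar <= 0 || peak_nbar > 1, "'peak_nbar' must be in (0, 1]")
  stop_if(radius_mm < 0, "'radius_mm' must be >= 0")
  out <- array(0, d)
  if (radius_mm <= spacing / 2) {
    out[center[1], center[2], center[3]] <- peak_nbar
    return(fk_state(out, 0))
  }
  sigma <- radius_mm / 2
  co <- lapply(1:3, function(k) ((seq_len(d[k]) - center[k]) * spacing)^2)
  d2 <- outer(outer(co[[1]], co[[2]], "+"), co[[3]], "+")
  edge <- exp(-radius_mm^2 / (2 * sigma^2))
  prof <- peak_nbar * pmax(0, exp(-d2 / (2 * sigma^2)) - edge) / (1 - edge)
  prof[d2 > radius_mm^2] <- 0
  prof[!prostate] <- 0
  fk_state(array(prof, d), 0)
}

# proliferation activity of a raw density field under rate rho
true_ap <- function(nbar, rho, nbar_th) {
  reg <- nbar >= nbar_th
  if (!any(reg)) return(0)
  mean(rho * nbar[reg] * (1 - nbar[reg]))
}

#' Generate one synthetic patient
#'
#' Draws the patient's prostate geometry, true growth parameters and scan
#' schedule from the cohort specification, forward-simulates the density
#' with the Fisher-Kolmogorov model to the scan times, converts density to
#' ADC ratio (exact inverse of the density conversion, \code{adc_h = 1}),
#' adds truncated Gaussian noise, rebuilds the measured density maps through
#' the ADC conversion, derives gross tumor masks by 3-mm dilation of the
#' tumor region, and assigns a Gleason-like risk label from the true
#' proliferation activity at the last scan.
#'
#' Uses the current RNG state; call \code{set.seed()} (or use
#' [generate_cohort()]) for reproducibility.
#'
#' @param spec a [cohort_spec()].
#' @param id patient identifier (integer).
#' @return List of class \code{"synthetic_patient"}: \code{id},
#'   \code{true_params}, \code{series} (a [scan_series()] of measured
#'   density + ADC + masks), \code{true_density} (noise-free simulated
#'   states), and \code{gs} (one-row data frame with the risk label).
#' @export
generate_patient <- function(spec, id = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  vol <- runif(1, spec$prostate_volume_range[1], spec$prostate_volume_range[2])
  prostate <- make_prostate(vol, spec$dim, spec$spacing)
  D <- exp(runif(1, log(spec$D_range[1]), log(spec$D_range[2])))
  rho <- exp(runif(1, log(spec$rho_range[1]), log(spec$rho_range[2])))
  gaps <- runif(spec$n_scans - 1L, spec$gap_range_years[1],
                spec$gap_range_years[2]) * 365.25
  times <- round(cumsum(c(0, gaps)))
  # tumor centre: offset from the prostate centre, pulled inside if needed
  ctr <- (spec$dim + 1) / 2
  u <- rnorm(3); u <- u / sqrt(sum(u^2))
  ratios <- c(1.25, 1, 0.85)
  s <- (3 * vol * 1000 / (4 * pi * prod(ratios)))^(1 / 3)
  off <- 0.35 * ratios * s * u / spec$spacing
  center <- as.integer(round(ctr + off))
  while (!prostate[center[1], center[2], center[3]]) {
    off <- off * 0.8
    center <- as.integer(round(ctr + off))
  }
  radius <- runif(1, spec$tumor_radius_range[1], spec$tumor_radius_range[2])
  peak <- runif(1, spec$tumor_peak_range[1], spec$tumor_peak_range[2])
  init <- seed_tumor(prostate, center, radius, peak, spec$spacing)
  grid <- fk_grid(prostate, spec$spacing, spec$dt)
  params <- growth_params(D, rho, spec$nbar_th)
  sim <- fk_simulate(init, grid, params, times = times[-1], t0 = 0)
  true_density <- c(list(init), sim)
  cal <- adc_calibration(adc_h = 1)
  noise_draws <- if (spec$noise_sd > 0)
    lapply(seq_len(spec$n_scans),
           function(i) array(rnorm(prod(spec$dim), 0, spec$noise_sd), spec$dim))
  adc <- vector("list", spec$n_scans)
  density <- vector("list", spec$n_scans)
  gross <- vector("list", spec$n_scans)
  for (i in seq_len(spec$n_scans)) {
    a <- array(cal$adc_h, spec$dim)  # healthy background
    a[prostate] <- density_to_adc(true_density[[i]]$nbar[prostate], cal)
    if (spec$noise_sd > 0)
      a <- pmin(pmax(a + noise_draws[[i]], 1e-6), 1.2)
    adc[[i]] <- a
    dens <- array(0, spec$dim)
    dens[prostate] <- adc_to_density(a[prostate], cal)
    density[[i]] <- dens
    gross[[i]] <- expand_margin(true_density[[i]]$nbar >= spec$nbar_th,
                                prostate, 3, spec$spacing)
  }
  ap <- true_ap(true_density[[spec$n_scans]]$nbar, rho, spec$nbar_th)
  higher <- ap > spec$ap_cutoff
  gs <- data.frame(time_days = times[spec$n_scans],
                   gs_primary = 3L, gs_secondary = if (higher) 4L else 3L,
                   a_p_true = ap,
                   gs_label = if (higher) "higher_risk" else "lower_risk")
  structure(list(id = as.integer(id), true_params = params,
                 series = scan_series(times, density, adc = adc,
                                      prostate = prostate, gross = gross),
                 true_density = true_density, gs = gs,
                 spacing = spec$spacing, dt = spec$dt),
            class = "synthetic_patient")
}

#' @export
print.synthetic_patient <- function(x, ...) {
  cat(sprintf("synthetic_patient %d: D = %.3g mm^2/day, rho = %.3g 1/day, %d scans over %g days, %s\n",
              x$id, x$true_params$D, x$true_params$rho,
              length(x$series$times), max(x$series$times), x$gs$gs_label))
  invisible(x)
}

#' Generate a synthetic cohort
#'
#' Seeds the RNG from \code{spec$seed} and generates \code{spec$n_patients}
#' patients; with a fixed seed the cohort is bit-reproducible.
#'
#' @param spec a [cohort_spec()].
#' @return List of \code{synthetic_patient} objects, class
#'   \code{"synthetic_cohort"}.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  structure(lapply(seq_len(spec$n_patients), function(i)
    generate_patient(spec, id = i)),
    class = "synthetic_cohort", spec = spec)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort of %d patients (%d higher-risk)\n", length(x),
              sum(vapply(x, function(p) p$gs$gs_label == "higher_risk", TRUE))))
  invisible(x)
}

#' Write / read a cohort directory
#'
#' Serializes a synthetic cohort to a directory tree: per-patient NIfTI
#' volumes (ADC, measured density, prostate and gross masks), a
#' \code{scans.json} with times, \code{adc_h}, the risk label and the true
#' parameters, and a \code{cohort.csv} manifest.
#'
#' @param cohort a \code{synthetic_cohort}.
#' @param dir output directory (created if needed).
#' @return \code{write_cohort()} returns \code{dir} invisibly;
#'   \code{read_cohort()} returns a \code{synthetic_cohort}.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  spec <- attr(cohort, "spec")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- data.frame()
  for (p in cohort) {
    pd <- file.path(dir, sprintf("patient_%02d", p$id))
    dir.create(pd, showWarnings = FALSE)
    sp <- spec$spacing
    write_nifti_volume(p$series$prostate, file.path(pd, "prostate_mask.nii.gz"), sp)
    for (i in seq_along(p$series$times)) {
      write_nifti_volume(p$series$adc[[i]],
                         file.path(pd, sprintf("scan_%d_adc.nii.gz", i)), sp)
      write_nifti_volume(p$series$density[[i]],
                         file.path(pd, sprintf("scan_%d_density.nii.gz", i)), sp)
      write_nifti_volume(p$series$gross[[i]],
                         file.path(pd, sprintf("scan_%d_gross.nii.gz", i)), sp)
    }
    meta <- list(id = p$id, times_days = p$series$times, adc_h = 1,
                 spacing_mm = sp, dt_days = spec$dt,
                 true_D = p$true_params$D, true_rho = p$true_params$rho,
                 gs_label = p$gs$gs_label, gs_time_days = p$gs$time_days,
                 a_p_true = p$gs$a_p_true)
    jsonlite::write_json(meta, file.path(pd, "scans.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest <- rbind(manifest,
                      data.frame(patient = p$id,
                                 dir = sprintf("patient_%02d", p$id),
                                 n_scans = length(p$series$times),
                                 gs_label = p$gs$gs_label))
  }
  write.csv(manifest, file.path(dir, "cohort.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  manifest <- read.csv(file.path(dir, "cohort.csv"))
  pats <- lapply(seq_len(nrow(manifest)), function(r) {
    pd <- file.path(dir, manifest$dir[r])
    meta <- jsonlite::read_json(file.path(pd, "scans.json"), simplifyVector = TRUE)
    sp <- meta$spacing_mm
    prostate <- read_nifti_volume(file.path(pd, "prostate_mask.nii.gz"))$data > 0
    ns <- length(meta$times_days)
    adc <- lapply(seq_len(ns), function(i)
      read_nifti_volume(file.path(pd, sprintf("scan_%d_adc.nii.gz", i)))$data)
    density <- lapply(seq_len(ns), function(i)
      read_nifti_volume(file.path(pd, sprintf("scan_%d_density.nii.gz", i)))$data)
    gross <- lapply(seq_len(ns), function(i)
      read_nifti_volume(file.path(pd, sprintf("scan_%d_gross.nii.gz", i)))$data > 0)
    structure(list(id = meta$id,
                   true_params = growth_params(meta$true_D, meta$true_rho),
                   series = scan_series(meta$times_days, density, adc = adc,
                                        prostate = prostate, gross = gross),
                   true_density = NULL,
                   gs = data.frame(time_days = meta$gs_time_days,
                                   a_p_true = meta$a_p_true,
                                   gs_label = meta$gs_label),
                   spacing = sp, dt = meta$dt_days),
              class = "synthetic_patient")
  })
  structure(pats, class = "synthetic_cohort")
}
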