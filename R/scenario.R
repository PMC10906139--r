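#' Run a cohort study scenario end to end
#'
#' Orchestrates the two computational scenarios of the study over a cohort.
#' In \code{"global_calibration"} the growth model is calibrated to all
#' scans of each patient (representation); in \code{"fitting_forecasting"}
#' it is calibrated to the first two scans only and the personalized
#' forecast is validated against the remaining scan(s) (prediction). For
#' every patient the function calibrates [fk_fit()], simulates to each scan
#' time, assembles per-scan [agreement_report()] rows and
#' [biomarker_panel()] rows (at the scan times, which stand in for the
#' histopathology times), computes cohort-level concordance of measured vs
#' model tumor volumes at the last scan, and -- when both risk classes are
#' present -- trains the univariate proliferation-activity logistic
#' classifier and evaluates per-patient risk trajectories. All computations
#' are deterministic given the cohort.
#'
#' @param cohort a \code{synthetic_cohort} (from [generate_cohort()] or
#'   [read_cohort()]), or any list of patients with elements \code{series},
#'   \code{spacing}, \code{dt}, and optionally \code{gs}.
#' @param scenario \code{"global_calibration"} or
#'   \code{"fitting_forecasting"}.
#' @param nbar_th tumor-region threshold; default 0.15.
#' @param control a [fk_control()] list.
#' @param classifier_features biomarker column(s) for the risk classifier;
#'   default \code{"a_p"}.
#' @param output_dir if non-NULL, agreement and biomarker CSVs plus
#'   calibration and classifier JSON are written there (inputs are never
#'   modified).
#' @return Object of class \code{"fk_scenario"}: \code{agreement} and
#'   \code{biomarkers} data frames, per-patient \code{fits},
#'   \code{cohort_concordance} (PCC/CCC of \eqn{V_T} and \eqn{V_N} at the
#'   last scan), \code{classifier} (or NULL), and \code{risk_trajectories}.
#' @export
run_scenario <- function(cohort,
                         scenario = c("global_calibration", "fitting_forecasting"),
                         nbar_th = 0.15, control = fk_control(),
                         classifier_features = "a_p",
                         output_dir = NULL) {
  scenario <- match.arg(scenario)
  agreement <- data.frame()
  biomarkers <- data.frame()
  fits <- list()
  skipped <- character()
  for (p in cohort) {
    ns <- length(p$series$times)
    if (scenario == "fitting_forecasting" && ns < 3L) {
      skipped <- c(skipped, sprintf(
        "patient %s: fitting_forecasting needs >= 3 scans, has %d", p$id, ns))
      next
    }
    grid <- fk_grid(p$series$prostate, p$spacing, p$dt)
    fit_series <- if (scenario == "fitting_forecasting")
      scan_series(p$series$times[1:2], p$series$density[1:2])
    else scan_series(p$series$times, p$series$density)
    fit <- fk_fit(fit_series, grid, control = control)
    fits[[as.character(p$id)]] <- fit
    sim <- fk_simulate(p$series$density[[1]], grid, fit$params,
                       times = p$series$times[-1], t0 = p$series$times[1],
                       control = control$solver)
    for (i in seq_len(ns - 1L)) {
      arow <- agreement_report(fk_state(p$series$density[[i + 1L]],
                                       p$series$times[i + 1L]),
                              sim[[i]], grid, nbar_th)
      arow <- cbind(data.frame(patient = p$id, scenario = scenario,
                              scan_index = i + 1L,
                              horizon = if (scenario == "fitting_forecasting" &&
                                            i + 1L > 2L) "forecast" else "calibration"),
                   arow)
      agreement <- rbind(agreement, arow)
    }
    states <- c(list(fk_state(p$series$density[[1]], p$series$times[1])), sim)
    for (i in seq_len(ns)) {
      bp <- biomarker_panel(states[[i]], grid, fit$params, nbar_th)
      bp <- cbind(data.frame(patient = p$id, scenario = scenario,
                             scan_index = i,
                             gs_label = if (!is.null(p$gs)) p$gs$gs_label[1]
                             else NA_character_),
                  bp)
      biomarkers <- rbind(biomarkers, bp)
    }
  }
  stop_if(nrow(agreement) == 0L, "no patient satisfied the scenario's scan requirement")
  last <- agreement[agreement$scan_index ==
                      stats::ave(agreement$scan_index, agreement$patient,
                                 FUN = max), ]
  concord <- if (nrow(last) >= 3L)
    list(v_t = cohort_concordance(last$v_t_meas, last$v_t_model),
         v_n = cohort_concordance(last$v_n_meas, last$v_n_model))
  final_bio <- biomarkers[biomarkers$scan_index ==
                            stats::ave(biomarkers$scan_index,
                                       biomarkers$patient, FUN = max), ]
  classifier <- NULL
  risk_traj <- NULL
  if (!all(is.na(final_bio$gs_label)) &&
      sum(final_bio$gs_label == "higher_risk", na.rm = TRUE) >= 2L &&
      sum(final_bio$gs_label == "lower_risk", na.rm = TRUE) >= 2L) {
    classifier <- fit_logistic(final_bio, classifier_features)
    risk_traj <- lapply(fits, function(f) {
      times <- seq(f$series$times[1], max(f$series$times), length.out = 13)
      st <- c(list(fk_state(f$series$density[[1]], f$series$times[1])),
              predict(f, times = times[-1]))
      risk_trajectory(st, f$grid, f$params, classifier, nbar_th)
    })
  }
  res <- structure(list(scenario = scenario, agreement = agreement,
                        biomarkers = biomarkers, fits = fits,
                        cohort_concordance = concord,
                        classifier = classifier,
                        risk_trajectories = risk_traj,
                        skipped = skipped),
                   class = "fk_scenario")
  if (!is.null(output_dir)) write_scenario(res, output_dir)
  res
}

#' @export
print.fk_scenario <- function(x, ...) {
  cat(sprintf("fk_scenario '%s': %d patients fitted, %d skipped\n",
              x$scenario, length(x$fits), length(x$skipped)))
  if (!is.null(x$cohort_concordance)) {
    cc <- x$cohort_concordance
    cat(sprintf("  cohort V_T agreement at last scan: PCC %.3f, CCC %.3f\n",
                cc$v_t[["pcc"]], cc$v_t[["ccc"]]))
    cat(sprintf("  cohort V_N agreement at last scan: PCC %.3f, CCC %.3f\n",
                cc$v_n[["pcc"]], cc$v_n[["ccc"]]))
  }
  if (!is.null(x$classifier))
    cat(sprintf("  risk classifier {%s}: AUC %.3f\n",
                paste(x$classifier$features, collapse = ", "),
                x$classifier$auc))
  for (s in x$skipped) cat("  skipped -", s, "\n")
  invisible(x)
}

# CSV/JSON serialization of a scenario run; outputs only, inputs untouched
write_scenario <- function(res, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(res$agreement, file.path(output_dir, "agreement.csv"),
            row.names = FALSE)
  write.csv(res$biomarkers, file.path(output_dir, "biomarkers.csv"),
            row.names = FALSE)
  calib <- lapply(res$fits, function(f)
    list(D = f$params$D, rho = f$params$rho, objective = f$objective,
         iterations = f$iterations, converged = f$converged))
  jsonlite::write_json(calib, file.path(output_dir, "calibration.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(res$classifier)) {
    cl <- res$classifier
    jsonlite::write_json(
      list(features = cl$features,
           coefficients = as.list(cl$coefficients),
           auc = cl$auc, separation = cl$separation,
           optimal_point = cl$optimal_point),
      file.path(output_dir, "classifier.json"),
      auto_unbox = TRUE, digits = NA)
    traj <- do.call(rbind, lapply(names(res$risk_trajectories), function(id)
      cbind(data.frame(patient = id),
            res$risk_trajectories[[id]])))
    write.csv(traj, file.path(output_dir, "risk_trajectories.csv"),
              row.names = FALSE)
  }
  invisible(output_dir)
}
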