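#' Prostate volume
#'
#' Volume of the masked prostate domain \eqn{\Omega} in cc.
#'
#' @param grid an [fk_grid()].
#' @return Prostate volume \eqn{V_P} in cc.
#' @export
prostate_volume <- function(grid) {
  stopifnot(inherits(grid, "fk_grid"))
  length(grid$index) * grid$spacing^3 / 1000
}

#' Model-based biomarker panel
#'
#' The six candidate markers of higher-risk disease evaluated on a density
#' state: prostate volume \eqn{V_P}, tumor volume \eqn{V_T}, total tumor
#' cell volume \eqn{V_N}, mean normalized density over the tumor region
#' \eqn{\bar N_{mean} = V_N / V_T}, the total tumor index
#' \eqn{N_T = V_N / V_P} (dimensionless, combining cellularity, tumor size
#' and organ size), and the mean proliferation activity
#' \eqn{A_p = \frac{1}{V_T}\int_{\Omega_T} \rho \bar N (1 - \bar N)\, dx}
#' in 1/day, the volume-averaged logistic growth term. \eqn{A_p} peaks at
#' \eqn{\bar N = 0.5} and vanishes in saturated (\eqn{\bar N = 1}) or empty
#' tissue. If the tumor region is empty all tumor markers are 0.
#'
#' @param state an [fk_state()] (a measured map or a model simulation).
#' @param grid an [fk_grid()].
#' @param params a [growth_params()] supplying \eqn{\rho}.
#' @param nbar_th tumor-region threshold; default 0.15.
#' @return One-row data frame: \code{time_days}, \code{v_p}, \code{v_t},
#'   \code{v_n}, \code{nbar_mean}, \code{n_t}, \code{a_p}.
#' @export
biomarker_panel <- function(state, grid, params, nbar_th = 0.15) {
  stopifnot(inherits(grid, "fk_grid"), inherits(params, "growth_params"))
  nbar <- if (inherits(state, "fk_state")) state$nbar else state
  t <- if (inherits(state, "fk_state")) state$t else NA_real_
  vp <- prostate_volume(grid)
  reg <- nbar >= nbar_th
  if (!any(reg))
    return(data.frame(time_days = t, v_p = vp, v_t = 0, v_n = 0,
                      nbar_mean = 0, n_t = 0, a_p = 0))
  vox_cc <- grid$spacing^3 / 1000
  vt <- sum(reg) * vox_cc
  vn <- sum(nbar[reg]) * vox_cc
  data.frame(time_days = t, v_p = vp, v_t = vt, v_n = vn,
             nbar_mean = vn / vt, n_t = vn / vp,
             a_p = mean(params$rho * nbar[reg] * (1 - nbar[reg])))
}

#' Logistic risk classifier from model-based biomarkers
#'
#' Fits a univariate or bivariate logistic regression of the higher-risk
#' label on 1-2 biomarkers by iteratively reweighted least squares (at most
#' two markers, to avoid overfitting on small cohorts), then runs ROC
#' analysis on the in-sample predicted probabilities. Perfect separation is
#' detected by capping the coefficient norm (on internally standardized
#' features) at 30 and flagging the fit; probabilities remain well defined.
#' Training and evaluation use the same cohort (no data split) -- a known
#' limitation of small-cohort studies that callers should keep in mind.
#'
#' @param panels data frame of biomarker rows, one per observation,
#'   containing the feature columns and a label column: either \code{risk}
#'   (0/1 or logical, 1 = higher risk) or \code{gs_label} with values
#'   \code{"lower_risk"}/\code{"higher_risk"}.
#' @param features character vector of 1 or 2 column names (e.g.,
#'   \code{"a_p"}, \code{c("a_p", "n_t")}).
#' @return Object of class \code{"risk_classifier"}: coefficients on the
#'   original feature scale, ROC curve, trapezoidal AUC, the optimal
#'   operating point (minimum distance to the (0, 1) corner), the
#'   log-likelihood, and a \code{separation} flag. Supports \code{print}
#'   and \code{predict(..., newdata)}.
#' @export
fit_logistic <- function(panels, features) {
  stop_if(!is.data.frame(panels), "'panels' must be a data frame")
  stop_if(length(features) < 1L || length(features) > 2L,
          "use 1 or 2 features (more would overfit small cohorts)")
  stop_if(!all(features %in% names(panels)), "missing feature columns")
  y <- if ("risk" %in% names(panels)) as.numeric(panels$risk > 0)
  else if ("gs_label" %in% names(panels))
    as.numeric(panels$gs_label == "higher_risk")
  else stop("'panels' needs a 'risk' or 'gs_label' column", call. = FALSE)
  stop_if(sum(y == 1) < 2L || sum(y == 0) < 2L,
          "need at least 2 observations per risk class")
  X <- as.matrix(panels[, features, drop = FALSE])
  stop_if(any(!is.finite(X)), "features must be finite")
  mu <- colMeans(X)
  sdev <- apply(X, 2, sd)
  sdev[sdev == 0] <- 1
  Z <- cbind(1, sweep(sweep(X, 2, mu), 2, sdev, "/"))
  beta <- numeric(ncol(Z))
  cap <- 30
  separation <- FALSE
  ll <- function(b) {
    eta <- drop(Z %*% b)
    sum(y * eta - log1p(exp(eta)))
  }
  ll_old <- ll(beta)
  for (it in 1:100) {
    eta <- drop(Z %*% beta)
    p <- plogis(eta)
    w <- pmax(p * (1 - p), 1e-10)
    zres <- eta + (y - p) / w
    bnew <- tryCatch(
      solve(crossprod(Z, Z * w), crossprod(Z, w * zres)),
      error = function(e) NULL)
    if (is.null(bnew)) break
    bnew <- drop(bnew)
    # step-halve to keep the log-likelihood non-decreasing
    step <- 1
    while (ll((1 - step) * beta + step * bnew) < ll_old - 1e-12 &&
           step > 1e-4) step <- step / 2
    bnew <- (1 - step) * beta + step * bnew
    if (sqrt(sum(bnew^2)) > cap) {
      beta <- bnew * cap / sqrt(sum(bnew^2))
      separation <- TRUE
      break
    }
    delta <- max(abs(bnew - beta))
    beta <- bnew
    ll_old <- ll(beta)
    if (delta < 1e-10) break
  }
  # back-transform to the raw feature scale
  slopes <- beta[-1] / sdev
  intercept <- beta[1] - sum(beta[-1] * mu / sdev)
  coefs <- setNames(c(intercept, slopes), c("(Intercept)", features))
  prob <- plogis(drop(cbind(1, X) %*% coefs))
  roc <- roc_analysis(prob, y)
  structure(list(features = features, coefficients = coefs,
                 separation = separation, loglik = ll(beta),
                 roc = roc$roc, auc = roc$auc,
                 optimal_point = roc$optimal_point,
                 fitted = prob, labels = y),
            class = "risk_classifier")
}

#' @export
print.risk_classifier <- function(x, ...) {
  cat(sprintf("Logistic risk classifier on {%s}%s\n",
              paste(x$features, collapse = ", "),
              if (x$separation) " [perfect separation: coefficients capped]" else ""))
  print(signif(x$coefficients, 4))
  cat(sprintf("AUC (trapezoidal): %.3f; optimal point: sensitivity %.1f%%, specificity %.1f%% at p >= %.3g\n",
              x$auc, 100 * x$optimal_point$sensitivity,
              100 * x$optimal_point$specificity, x$optimal_point$threshold))
  invisible(x)
}

#' @export
predict.risk_classifier <- function(object, newdata, ...) {
  X <- as.matrix(newdata[, object$features, drop = FALSE])
  plogis(drop(cbind(1, X) %*% object$coefficients))
}

#' ROC curve, trapezoidal AUC and optimal operating point
#'
#' Sweeps every distinct score value (plus open endpoints) as a threshold,
#' calling higher scores higher-risk, computes the (FPR, TPR) curve, the
#' area under it by the trapezoidal rule, and the optimal operating point as
#' the ROC vertex of minimum Euclidean distance to the upper-left corner
#' (FPR 0, TPR 1); distance ties are broken toward higher sensitivity.
#'
#' @param scores numeric classifier scores.
#' @param labels 0/1 (or logical) true classes, 1 = positive/higher risk.
#' @return List with \code{roc} (data frame \code{threshold}, \code{fpr},
#'   \code{tpr}), \code{auc}, and \code{optimal_point} (list with
#'   \code{sensitivity}, \code{specificity}, \code{threshold}).
#' @examples
#' roc_analysis(c(0.1, 0.4, 0.45, 0.8), c(0, 1, 0, 1))$auc  # 0.75
#' @export
roc_analysis <- function(scores, labels) {
  y <- as.numeric(labels > 0)
  stop_if(length(scores) != length(y), "lengths differ")
  stop_if(sum(y == 1) == 0L || sum(y == 0) == 0L,
          "both classes must be present")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  np <- sum(y == 1); nn <- sum(y == 0)
  tpr <- vapply(thr, function(th) sum(scores >= th & y == 1) / np, 0)
  fpr <- vapply(thr, function(th) sum(scores >= th & y == 0) / nn, 0)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  d2 <- fpr^2 + (1 - tpr)^2
  cand <- which(d2 <= min(d2) + 1e-12)
  best <- cand[which.max(tpr[cand])]
  list(roc = data.frame(threshold = thr, fpr = fpr, tpr = tpr),
       auc = auc,
       optimal_point = list(sensitivity = tpr[best],
                            specificity = 1 - fpr[best],
                            threshold = thr[best]))
}

#' Risk-probability trajectory along a simulation
#'
#' Evaluates the biomarker panel on each simulated density state, feeds it
#' through a fitted risk classifier, and reports the probability of
#' higher-risk disease over time together with the first time it crosses the
#' classifier's optimal-point threshold (the predicted progression time;
#' \code{NA} if never crossed).
#'
#' @param states list of [fk_state()] objects (e.g., from
#'   \code{predict(fit, times)}).
#' @param grid an [fk_grid()].
#' @param params a [growth_params()] used for \eqn{A_p}.
#' @param classifier a fitted [fit_logistic()] object.
#' @param nbar_th tumor-region threshold.
#' @return Data frame with \code{time_days}, the panel columns, and
#'   \code{risk_prob}; attribute \code{"progression_time"} holds the
#'   threshold-crossing time in days.
#' @export
risk_trajectory <- function(states, grid, params, classifier, nbar_th = 0.15) {
  stopifnot(inherits(classifier, "risk_classifier"))
  rows <- do.call(rbind, lapply(states, biomarker_panel, grid = grid,
                                params = params, nbar_th = nbar_th))
  rows$risk_prob <- predict(classifier, rows)
  crossed <- which(rows$risk_prob >= classifier$optimal_point$threshold)
  attr(rows, "progression_time") <-
    if (length(crossed)) rows$time_days[crossed[1]] else NA_real_
  rows
}
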