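test_that("prostate volume converts voxel counts to cc", {
  m <- array(FALSE, c(40, 40, 40))
  m[seq_len(36400)] <- TRUE
  g <- fk_grid(m, 1)
  expect_equal(prostate_volume(g), 36.4)
  g2 <- fk_grid(m, 2)
  expect_equal(prostate_volume(g2), 8 * 36.4)   # doubling spacing: 8x volume
  m1 <- array(FALSE, c(3, 3, 3)); m1[1, 1, 1] <- TRUE
  expect_equal(prostate_volume(fk_grid(m1, 1)), 0.001)
})

test_that("biomarker panel matches hand evaluations", {
  d <- c(40, 40, 40)
  m <- array(FALSE, d); m[seq_len(40000)] <- TRUE
  g <- fk_grid(m, 1)  # 40 cc prostate
  nbar <- array(0, d)
  nbar[which(m)[seq_len(1000)]] <- 0.4  # 1 cc tumor region, uniform 0.4
  p <- growth_params(1e-3, 2e-3)
  bp <- biomarker_panel(fk_state(nbar, 0), g, p)
  expect_equal(bp$v_p, 40)
  expect_equal(bp$v_t, 1)
  expect_equal(bp$v_n, 0.4)
  expect_equal(bp$nbar_mean, 0.4)
  expect_equal(bp$n_t, 0.01)
  expect_equal(bp$a_p, 2e-3 * 0.4 * 0.6)
  # uniform 0.5: a_p = rho/4
  nbar05 <- array(0, d); nbar05[m] <- 0.5
  expect_equal(biomarker_panel(nbar05, g, p)$a_p, 2e-3 * 0.25)
  # saturated tumor: proliferation shuts down
  nbar1 <- array(0, d); nbar1[m] <- 1
  bp1 <- biomarker_panel(nbar1, g, p)
  expect_equal(bp1$a_p, 0)
  expect_equal(bp1$nbar_mean, 1)
  # empty tumor region
  bp0 <- biomarker_panel(array(0, d), g, p)
  expect_equal(c(bp0$v_t, bp0$v_n, bp0$nbar_mean, bp0$n_t, bp0$a_p),
               rep(0, 5))
})

test_that("voxelwise proliferation activity peaks at density 0.5", {
  f <- function(n) n * (1 - n)
  expect_true(all(f(0.5) > f(c(0, 0.1, 0.3, 0.7, 0.9, 1))))
  expect_equal(f(0), 0); expect_equal(f(1), 0)
})

test_that("logistic fit agrees with glm on non-separated data", {
  set.seed(81)
  x <- rnorm(40)
  y <- rbinom(40, 1, plogis(-0.5 + 1.2 * x))
  panels <- data.frame(a_p = x, risk = y)
  fit <- fit_logistic(panels, "a_p")
  ref <- glm(y ~ x, family = binomial)
  expect_false(fit$separation)
  expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-5)
  # bivariate
  z <- rnorm(40)
  pan2 <- data.frame(a_p = x, n_t = z,
                     risk = rbinom(40, 1, plogis(x - z)))
  fit2 <- fit_logistic(pan2, c("a_p", "n_t"))
  ref2 <- glm(pan2$risk ~ x + z, family = binomial)
  expect_equal(unname(fit2$coefficients), unname(coef(ref2)), tolerance = 1e-5)
})

test_that("fitted log-likelihood is no worse than a coefficient grid search", {
  set.seed(91)
  x <- rnorm(25)
  y <- rbinom(25, 1, plogis(0.8 * x))
  fit <- fit_logistic(data.frame(a_p = x, risk = y), "a_p")
  ll <- function(b0, b1) sum(y * (b0 + b1 * x) - log1p(exp(b0 + b1 * x)))
  grid_ll <- max(outer(seq(-3, 3, length.out = 50),
                       seq(-3, 3, length.out = 50), Vectorize(ll)))
  fit_ll <- ll(fit$coefficients[1], fit$coefficients[2])
  expect_gte(fit_ll, grid_ll - 1e-8)
})

test_that("perfect separation is detected, capped, and keeps the boundary", {
  panels <- data.frame(a_p = c(1, 2, 3, 4), risk = c(0, 0, 1, 1))
  fit <- fit_logistic(panels, "a_p")
  expect_true(fit$separation)
  expect_true(all(is.finite(fit$coefficients)))
  # symmetric data: decision boundary at the midpoint 2.5
  boundary <- -fit$coefficients[1] / fit$coefficients[2]
  expect_equal(unname(boundary), 2.5, tolerance = 1e-6)
  expect_equal(fit$auc, 1)
})

test_that("uninformative features give a near-zero slope", {
  panels <- data.frame(a_p = rep(1.5, 8), risk = c(0, 1, 0, 1, 0, 1, 0, 1))
  fit <- fit_logistic(panels, "a_p")
  expect_lt(abs(fit$coefficients[["a_p"]]), 1e-6)
})

test_that("classifier input validation", {
  panels <- data.frame(a_p = 1:4, n_t = 1:4, v_t = 1:4,
                       risk = c(0, 0, 1, 1))
  expect_error(fit_logistic(panels, c("a_p", "n_t", "v_t")), "overfit")
  expect_error(fit_logistic(data.frame(a_p = 1:4, risk = rep(1, 4)), "a_p"),
               "class")
})

test_that("a_p separates risk groups generated with higher proliferation", {
  # synthetic cohort labelled by true proliferation activity: the a_p
  # classifier must beat chance comfortably at this effect size
  co <- small_cohort()
  set.seed(101)
  lo <- rnorm(8, 2e-4, 3e-5)
  hi <- rnorm(8, 8e-4, 1e-4)
  panels <- data.frame(a_p = c(lo, hi), risk = rep(c(0, 1), each = 8))
  fit <- fit_logistic(panels, "a_p")
  expect_gt(fit$auc, 0.9)
  expect_gt(fit$coefficients[["a_p"]], 0)
})

test_that("risk trajectories are monotone for growing markers and report crossing", {
  # uniform density growing in time so that n_t grows monotonically
  d <- c(6, 6, 6)
  g <- full_grid(d)
  params <- growth_params(1e-3, 2e-3)
  levels <- seq(0.2, 0.45, length.out = 8)
  states <- lapply(seq_along(levels), function(i)
    fk_state(array(levels[i], d), t = (i - 1) * 100))
  # classifier with positive weight on a growing marker
  set.seed(111)
  pan <- data.frame(n_t = c(rnorm(6, 0.25, 0.02), rnorm(6, 0.4, 0.02)),
                    risk = rep(c(0, 1), each = 6))
  cl <- fit_logistic(pan, "n_t")
  traj <- risk_trajectory(states, g, params, cl)
  expect_equal(nrow(traj), length(states))
  expect_true(all(diff(traj$risk_prob) >= -1e-9))
  cross <- attr(traj, "progression_time")
  brute <- traj$time_days[which(traj$risk_prob >= cl$optimal_point$threshold)[1]]
  expect_identical(cross, brute)
  # constant density in time: constant risk probability
  cstates <- list(fk_state(array(0.3, d), 0),
                  fk_state(array(0.3, d), 100))
  ctraj <- risk_trajectory(cstates, g, params, cl)
  expect_equal(ctraj$risk_prob[1], ctraj$risk_prob[2])
})
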