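test_that("zero dynamics leave the state unchanged", {
  g <- full_grid(c(4, 4, 4))
  set.seed(2)
  n0 <- array(runif(64, 0, 0.9), c(4, 4, 4))
  s <- fk_step(fk_state(n0, 0), g, growth_params(0, 0))
  expect_equal(s$nbar, n0, tolerance = 1e-12)
  expect_equal(s$t, 1)
})

test_that("requesting the initial time returns the initial state", {
  g <- full_grid()
  n0 <- array(0.3, c(5, 5, 5))
  s <- fk_simulate(fk_state(n0, 5), g, growth_params(1e-3, 1e-3), times = 5)
  expect_equal(s[[1]]$nbar, n0)
  expect_equal(s[[1]]$t, 5)
})

test_that("pure logistic growth matches the closed form to 1e-3 over 1000 days", {
  g <- full_grid(c(4, 4, 4))
  rho <- 2e-3; n0v <- 0.1
  n0 <- array(n0v, c(4, 4, 4))
  times <- seq(50, 1000, by = 50)
  s <- fk_simulate(fk_state(n0, 0), g, growth_params(0, rho), times)
  closed <- n0v * exp(rho * times) / (1 + n0v * (exp(rho * times) - 1))
  got <- vapply(s, function(st) st$nbar[2, 2, 2], 0)
  expect_lt(max(abs(got - closed)), 1e-3)
  # field stays uniform: diffusion-free dynamics are pointwise
  expect_lt(max(vapply(s, function(st) diff(range(st$nbar)), 0)), 1e-12)
})

test_that("a single implicit step with D = 0 solves the logistic update", {
  g <- full_grid(c(3, 3, 3))
  rho <- 0.05; n0v <- 0.4
  s <- fk_step(fk_state(array(n0v, c(3, 3, 3)), 0), g, growth_params(0, rho))
  # backward-Euler update: u - n0 - dt*rho*u*(1-u) = 0, positive root
  a <- rho; b <- 1 - rho; cc <- -n0v
  u_exact <- (-b + sqrt(b^2 - 4 * a * cc)) / (2 * a)
  expect_equal(s$nbar[1, 1, 1], u_exact, tolerance = 1e-9)
})

test_that("zero-flux diffusion conserves total cell volume to 1e-10 over 1000 steps", {
  m <- make_prostate(25, c(20, 20, 20), 2.5)
  st <- seed_tumor(m, c(10, 10, 10), 8, 0.8, 2.5)
  g <- fk_grid(m, 2.5)
  s <- fk_simulate(st, g, growth_params(5e-3, 0), times = 1000)
  drift <- abs(sum(s[[1]]$nbar) - sum(st$nbar)) / sum(st$nbar)
  expect_lt(drift, 1e-10)
})

test_that("density stays within [0, 1] on random instances", {
  set.seed(9)
  for (rep in 1:4) {
    m <- make_prostate(20, c(16, 16, 16), 3)
    n0 <- array(0, c(16, 16, 16))
    n0[m] <- runif(sum(m))
    g <- fk_grid(m, 3)
    s <- fk_simulate(fk_state(n0, 0), g,
                     growth_params(10^runif(1, -4, -2), 10^runif(1, -4, -2)),
                     times = c(50, 400))
    for (st in s) expect_true(all(st$nbar >= 0 & st$nbar <= 1))
  }
})

test_that("1D front speed matches 2*sqrt(D*rho) within 5% at fine resolution", {
  h <- 0.125; nx <- 960; D <- 0.2; rho <- 0.2
  g <- fk_grid(array(TRUE, c(nx, 1, 1)), h, dt = 0.1)
  u <- array(0, c(nx, 1, 1)); u[seq_len(round(10 / h)), , ] <- 1
  times <- seq(100, 250, length.out = 8)
  s <- fk_simulate(fk_state(u, 0), g, growth_params(D, rho), times)
  front <- vapply(s, function(st) {
    v <- st$nbar[, 1, 1]
    i <- max(which(v >= 0.5))
    (i - 1) * h + h * (v[i] - 0.5) / (v[i] - v[i + 1])
  }, 0)
  speed <- unname(coef(lm(front ~ times))[2])
  expect_lt(abs(speed / (2 * sqrt(D * rho)) - 1), 0.05)
})

test_that("solution is independent of padding outside the domain", {
  m <- make_prostate(12, c(14, 14, 14), 3)
  st <- seed_tumor(m, c(7, 7, 7), 6, 0.7, 3)
  g <- fk_grid(m, 3)
  s1 <- fk_simulate(st, g, growth_params(2e-3, 3e-3), times = 200)[[1]]
  big <- array(FALSE, c(20, 20, 20)); big[3:16, 3:16, 3:16] <- m
  nb <- array(0, c(20, 20, 20)); nb[3:16, 3:16, 3:16] <- st$nbar
  g2 <- fk_grid(big, 3)
  s2 <- fk_simulate(fk_state(nb, 0), g2, growth_params(2e-3, 3e-3),
                    times = 200)[[1]]
  expect_equal(s2$nbar[3:16, 3:16, 3:16], s1$nbar, tolerance = 1e-12)
})

test_that("V_N changes < 2% under simultaneous grid and time refinement", {
  # smooth case: the travelling front (width sqrt(D/rho) = 5 mm) is resolved
  # on both grids, so the remaining error is the rim voxelization
  sim_vn <- function(h, dt, n) {
    m <- make_prostate(18, rep(n, 3), h)
    ctr <- rep((n + 1) / 2, 3)
    st <- seed_tumor(m, round(ctr), 9, 0.8, h)
    g <- fk_grid(m, h, dt = dt)
    s <- fk_simulate(st, g, growth_params(0.05, 2e-3), times = 300)[[1]]
    total_cell_volume(s, g)
  }
  coarse <- sim_vn(2, 2, 24)
  fine <- sim_vn(1, 1, 44)
  expect_lt(abs(fine / coarse - 1), 0.02)
})

test_that("growth_params validates the admissible boxes", {
  expect_error(growth_params(11, 1e-3), "admissible")
  expect_error(growth_params(1e-3, 2), "admissible")
  expect_error(growth_params(1e-8, 1e-3), "admissible")
  expect_silent(growth_params(0, 0))       # degenerate dynamics allowed
  expect_error(growth_params(1e-3, 1e-3, nbar_th = 1.5), "nbar_th")
})

test_that("simulate validates its inputs", {
  g <- full_grid()
  n0 <- array(0.2, c(5, 5, 5))
  p <- growth_params(1e-3, 1e-3)
  expect_error(fk_simulate(n0, g, p, times = c(5, 2)), "sorted")
  expect_error(fk_simulate(fk_state(n0, 10), g, p, times = 5), ">=")
  bad <- n0; bad[1] <- 2
  expect_error(fk_state(bad, 0), "0, 1")
  off <- array(0.2, c(5, 5, 5)); off[1, 1, 1] <- 0.3
  gm <- fk_grid(array(c(FALSE, rep(TRUE, 124)), c(5, 5, 5)), 1)
  expect_error(fk_simulate(off, gm, p, times = 1), "outside")
})
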