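test_that("ADC-to-density conversion follows the linear map with truncation", {
  cal <- adc_calibration(adc_h = 1)
  expect_equal(adc_to_density(0.70, cal), 0.4)
  expect_identical(adc_to_density(1.0, cal), 0)      # at adc_h
  expect_identical(adc_to_density(1.1, cal), 0)      # truncated above
  expect_identical(adc_to_density(0.25, cal), 1)     # at adc_min
  expect_identical(adc_to_density(0.10, cal), 1)     # truncated below
  expect_equal(adc_to_density(0.90, cal), (1 - 0.90) / 0.75)
  # units carry through adc_h
  cal2 <- adc_calibration(adc_h = 1.4)
  expect_equal(adc_to_density(0.7 * 1.4, cal2), 0.4)
})

test_that("conversion is monotone non-increasing with range exactly [0, 1]", {
  cal <- adc_calibration(adc_h = 1.2)
  adc <- seq(-0.5, 2, length.out = 401)
  nb <- adc_to_density(adc, cal)
  expect_true(all(diff(nb) <= 1e-15))
  expect_true(all(nb >= 0 & nb <= 1))
  expect_equal(range(nb), c(0, 1))
})

test_that("density_to_adc is the exact inverse on [adc_min, adc_h]", {
  cal <- adc_calibration(adc_h = 1.3)
  n <- seq(0, 1, length.out = 101)
  expect_equal(adc_to_density(density_to_adc(n, cal), cal), n, tolerance = 1e-12)
  expect_identical(density_to_adc(0, cal), cal$adc_h)
  expect_equal(density_to_adc(1, cal), 0.25 * cal$adc_h)
  expect_equal(density_to_adc(0.4, cal), 0.70 * cal$adc_h)
  expect_error(density_to_adc(1.2, cal), "0, 1")
})

test_that("healthy-tissue ADC is the ROI mean and rejects empty regions", {
  a <- array(0, c(2, 2, 1))
  a[, , 1] <- c(1, 1, 3, 3)
  roi <- array(TRUE, c(2, 2, 1))
  expect_equal(estimate_healthy_adc(a, roi), 2)
  roi1 <- array(FALSE, c(2, 2, 1)); roi1[1, 2, 1] <- TRUE
  expect_equal(estimate_healthy_adc(a, roi1), a[1, 2, 1])
  expect_equal(estimate_healthy_adc(array(7, c(2, 2, 1)), roi), 7)
  expect_error(estimate_healthy_adc(a, array(FALSE, c(2, 2, 1))), "empty")
})

test_that("tumor core threshold is strict and confined to the gross mask", {
  cal <- adc_calibration(adc_h = 1)
  set.seed(1)
  adc <- array(runif(125, 0.4, 1.1), c(5, 5, 5))
  gross <- array(FALSE, c(5, 5, 5)); gross[2:4, 2:4, 2:4] <- TRUE
  # plant exactly 7 sub-threshold voxels inside gross
  adc[gross] <- 0.9
  low <- which(gross)[1:7]
  adc[low] <- 0.5
  core <- segment_tumor_core(adc, gross, cal)
  expect_identical(which(core), low)
  # a voxel exactly at 70% of adc_h is excluded (strict <)
  adc[low[1]] <- 0.70
  expect_equal(sum(segment_tumor_core(adc, gross, cal)), 6)
  expect_equal(sum(segment_tumor_core(adc, array(FALSE, c(5, 5, 5)), cal)), 0)
  expect_error(segment_tumor_core(adc, array(FALSE, c(4, 5, 5)), cal), "differ")
})

test_that("margin expansion dilates by a metric ball inside the gross mask", {
  d <- c(9, 9, 9)
  core <- array(FALSE, d); core[5, 5, 5] <- TRUE
  gross <- array(TRUE, d)
  # 2 mm ball at 1 mm spacing: lattice offsets with squared distance <= 4
  expect_equal(sum(expand_margin(core, gross, 2, 1)), 33)
  expect_identical(expand_margin(core, gross, 0, 1), core)
  expect_identical(expand_margin(core, core, 4, 1), core)  # clipped to gross
  expect_error(expand_margin(core, gross, -1, 1), ">= 0")
  # nested masks for growing margins
  prev <- core
  for (m in c(1, 2, 3.5)) {
    cur <- expand_margin(core, gross, m, 1)
    expect_true(all(prev <= cur))
    prev <- cur
  }
})

test_that("core shrinks as the ADC threshold tightens on random volumes", {
  set.seed(7)
  for (rep in 1:5) {
    adc <- array(runif(216, 0.2, 1.2), c(6, 6, 6))
    gross <- array(runif(216) < 0.5, c(6, 6, 6))
    sizes <- vapply(c(0.5, 0.6, 0.7, 0.8), function(cr) {
      sum(segment_tumor_core(adc, gross,
                             adc_calibration(adc_h = 1, core_ratio = cr)))
    }, 0)
    expect_true(all(diff(sizes) >= 0))
  }
})

test_that("tanh GS-ADC model recovers generating parameters on exact points", {
  gs <- seq(2, 9, by = 0.5)
  truth <- c(slope = 0.8, midpoint = 6)
  r <- 0.625 - 0.375 * tanh(truth["slope"] * (gs - truth["midpoint"]))
  fit <- fit_gs_adc_model(gs, r)
  expect_equal(fit$slope, 0.8, tolerance = 1e-6)
  expect_equal(fit$midpoint, 6, tolerance = 1e-6)
  expect_lt(fit$rss, 1e-12)
  # midpoint value and asymptotes
  expect_equal(predict(fit, fit$midpoint), 0.625)
  expect_equal(predict(fit, 0), 1, tolerance = 1e-2)
  expect_true(all(diff(predict(fit, seq(0, 10, 0.1))) < 0))
  expect_error(fit_gs_adc_model(c(1, 2), c(1, 0.9)), "3")
  expect_error(fit_gs_adc_model(c(3, 3, 3), c(1, 0.9, 0.8)), "degenerate")
})

test_that("shipped synthetic literature points fit a plausible sigmoid", {
  csv <- system.file("extdata", "gs_adc_literature_synthetic.csv",
                     package = "fkprost")
  pts <- read.csv(csv)
  fit <- fit_gs_adc_model(pts$gs, pts$adc_ratio)
  # threshold of ~70% of adc_h is reached within the tumor GS range
  gs70 <- uniroot(function(g) predict(fit, g) - 0.7, c(2, 10))$root
  expect_gt(gs70, 5); expect_lt(gs70, 7.5)
})

test_that("resampling preserves identity, constants and linear ramps", {
  v <- image_volume(array(rnorm(4^3), c(4, 4, 4)), spacing = 2)
  expect_identical(resample_isotropic(v, 2), v)
  vc <- image_volume(array(3.5, c(4, 5, 6)), spacing = 2)
  out <- resample_isotropic(vc, 0.9)
  expect_equal(max(abs(out$data - 3.5)), 0, tolerance = 1e-12)
  # ramp along x: halving the spacing must reproduce the linear function
  ramp <- image_volume(array(rep(0:7, 8 * 8), c(8, 8, 8)), spacing = 2)
  fine <- resample_isotropic(ramp, 1)
  xs <- (seq_len(dim(fine$data)[1]) - 1) * 1 / 2   # value = world_x / 2
  expect_equal(fine$data[, 1, 1], xs, tolerance = 1e-12)
  # midpoints are neighbour averages
  expect_equal(fine$data[2, 1, 1], (ramp$data[1, 1, 1] + ramp$data[2, 1, 1]) / 2)
  expect_error(resample_isotropic(v, -1), "> 0")
})

test_that("mask resampling is nearest-neighbour and stays binary", {
  m <- array(FALSE, c(6, 6, 6)); m[2:4, 2:4, 2:4] <- TRUE
  v <- image_volume(m, spacing = 2)
  out <- resample_isotropic(v, 1, method = "nearest")
  expect_type(out$data, "logical")
  expect_true(all(out$data %in% c(TRUE, FALSE)))
  expect_gt(sum(out$data), 0)
})

test_that("NIfTI round trip preserves data and spacing", {
  path <- withr::local_tempfile(fileext = ".nii.gz")
  v <- image_volume(array(runif(6^3), c(6, 6, 6)), spacing = 1.5)
  write_nifti_volume(v, path)
  back <- read_nifti_volume(path)
  expect_equal(back$data, v$data, tolerance = 1e-7)
  expect_equal(back$spacing, v$spacing)
})

test_that("preprocess_scan chains core, margin and conversion", {
  cal <- adc_calibration(adc_h = 1)
  d <- c(12, 12, 12)
  prostate <- array(TRUE, d)
  adc <- array(1, d)
  adc[5:8, 5:8, 5:8] <- 0.5
  gross <- expand_margin(adc < 0.9, prostate, 2, 1)
  pp <- preprocess_scan(adc, prostate, gross, cal, margin_mm = 2, spacing = 1)
  expect_true(all(pp$core <= pp$final))
  expect_true(all(pp$final <= gross))
  expect_equal(max(pp$density), adc_to_density(0.5, cal))
  expect_true(all(pp$density_tumor[!pp$final] == 0))
})
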