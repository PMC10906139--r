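# Shared fixtures, built once per test run and memoised. The small cohort
# uses a coarse grid so unit tests stay fast; the acceptance fixture uses the
# generator's default study conditions (48^3 grid at 1.5 mm, three scans).

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, build) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- build()
  .fixture_env[[key]]
}

# 3 noiseless patients on a 20^3 grid, short interscan gaps
small_cohort <- function() {
  memo("small_cohort", function() {
    generate_cohort(cohort_spec(
      n_patients = 3, dim = c(20, 20, 20), spacing = 2.5,
      prostate_volume_range = c(15, 25), gap_range_years = c(0.5, 1),
      noise_sd = 0, seed = 42))
  })
}

# the default 10-patient noiseless cohort at study conditions
acceptance_cohort <- function() {
  memo("acceptance_cohort", function() {
    generate_cohort(cohort_spec(noise_sd = 0, seed = 20260930))
  })
}

# fitting-forecasting run over the acceptance cohort (fits use scans 1-2
# only, so its fits double as the 2-scan calibration experiment)
acceptance_ff_run <- function() {
  memo("acceptance_ff_run", function() {
    run_scenario(acceptance_cohort(), "fitting_forecasting")
  })
}

# small toy grid helpers
full_grid <- function(dim = c(5, 5, 5), spacing = 1, dt = 1) {
  fk_grid(array(TRUE, dim), spacing, dt)
}
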