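# shared fixtures, built once per test run: a reduced design (5 sites, 18
# trips, 12 camera months) that keeps every structural feature of the full
# study while fitting in seconds, plus its fits and assembled SEM
.fixture_env <- new.env(parent = emptyenv())

small_design <- function() {
  generate_design(n_sites = 5, seed = 11, n_trips = 18, camera_months = 12)
}

small_sim <- function() {
  if (is.null(.fixture_env$sim)) {
    d <- small_design()
    .fixture_env$sim <- simulate_dataset(d, ground_truth(d), seed = 77)
  }
  .fixture_env$sim
}

small_fits <- function() {
  if (is.null(.fixture_env$fits)) {
    .fixture_env$fits <- suppressWarnings(suppressMessages(
      fit_all_nodes(canonical_graph(), small_sim()$frames)))
  }
  .fixture_env$fits
}

small_sem <- function() {
  if (is.null(.fixture_env$sem)) {
    .fixture_env$sem <- assemble(small_fits(), canonical_graph())
  }
  .fixture_env$sem
}

# a fitted_node skeleton with chosen deviances, for arithmetic checks
fake_fit <- function(deviance, null_deviance) {
  structure(list(name = "fake", deviance = deviance,
                 null_deviance = null_deviance),
            class = "fitted_node")
}
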