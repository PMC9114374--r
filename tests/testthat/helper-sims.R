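# Memoized reference simulations shared across test files. The staging
# run is the expensive fixture (150 x 150, 2,000 iterations); it is run
# once and reused, with an independent second run for the determinism
# check.

.sim_store <- new.env(parent = emptyenv())

sim_smoke <- function() {
  if (is.null(.sim_store$smoke)) {
    .sim_store$smoke <- run_simulation(reference_configs(seed = 1L)$smoke)
  }
  .sim_store$smoke
}

sim_staging <- function() {
  if (is.null(.sim_store$staging)) {
    .sim_store$staging <- run_simulation(reference_configs(seed = 1L)$staging,
                                         snapshot_every = 100)
  }
  .sim_store$staging
}

sim_staging_repeat <- function() {
  if (is.null(.sim_store$staging2)) {
    .sim_store$staging2 <- run_simulation(reference_configs(seed = 1L)$staging,
                                          snapshot_every = 100)
  }
  .sim_store$staging2
}

# straight trace with i.i.d. direction noise (degrees), unit headings
straight_noisy_trace <- function(n_steps, dir_sd_deg, step_len = 3,
                                 seed = 1L) {
  neurongrowth:::.with_seed(seed, {
    eta <- stats::rnorm(n_steps, 0, dir_sd_deg * pi / 180)
    as_trace(rbind(c(0, 0),
                   cbind(cumsum(step_len * cos(eta)),
                         cumsum(step_len * sin(eta)))))
  })
}
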