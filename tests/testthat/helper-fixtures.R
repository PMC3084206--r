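# Shared fixtures: everything is generated in code at test time.

# Cache expensive simulations across test files (helpers are sourced once
# per test_dir run).
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, force(expr), .fixture_cache)
  get(key, .fixture_cache)
}

dsm_trajectory <- function() {
  cached("dsm_traj", simulate_diauxic_growth(dsm_scenario()))
}

dsm_trajectory_noiseless <- function() {
  # same ODE truth; the noiseless flag only matters at the rendering stage
  dsm_trajectory()
}

dsm_analysis <- function(seed = 1, noise_cv = 0.02) {
  key <- sprintf("dsm_an_%d_%g", seed, noise_cv)
  cached(key, {
    scn <- dsm_scenario(noise_cv = noise_cv)
    run <- render_plate_run(dsm_trajectory(), scn, n_replicate_wells = 2,
                            seed = seed)
    analyze_plate_run(run, delta = log(2) / scn$reporter$half_life)
  })
}

# Minimal single-promoter scenario for reporter/arrest tests.
mini_scenario <- function(noise_cv = 0, duration = 3, ...) {
  scenario(
    medium = medium_spec(data.frame(name = "glc", conc = 1, mu_max = 0.9,
                                    K_s = 0.02, yield = 0.5)),
    rnap = rnap_params(),
    promoters = list(promoter_spec("P1", "constitutive", strength = 50,
                                   K_R = 0.3)),
    reporter = reporter_spec(),
    x0 = 0.05, duration = duration, noise_cv = noise_cv, name = "mini", ...)
}

expect_rel_error <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected)) / max(abs(expected)), tol)
}
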