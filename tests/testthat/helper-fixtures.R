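# Shared small fixtures, built once per test run. Sizes are kept small so
# the whole suite runs quickly; structural properties do not depend on scale.

make_fixture <- function(n_sources = 300, n_patches = 30, n_sensors = 48,
                         seed = 42, n_epochs = 60, epoch_duration = 0.3,
                         bumpiness = 0.1) {
  space <- build_sphere_source_space(n_sources, radius = 0.08,
                                     bumpiness = bumpiness, seed = seed)
  parc <- parcellate(space, n_patches, seed = seed)
  sensors <- sphere_sensor_array(n_sensors, radius = 0.12, seed = seed)
  gain <- build_gain(space, sensors)
  model <- brain_noise_model(gain, seed = seed)
  epochs <- simulate_epochs(model, n_epochs, epoch_duration, seed = seed)
  list(space = space, parc = parc, sensors = sensors, gain = gain,
       model = model, epochs = epochs)
}

fix_std <- make_fixture()

# balanced covariance from the held-out pool, as the pipeline builds it
fix_cov <- local({
  pools <- split_epochs(fix_std$epochs, 20, seed = 1)
  balance_covariance(fix_std$gain, estimate_covariance(pools$covariance))
})

# tiny random PD covariance for toy problems
toy_pd <- function(n, seed = 1) {
  withr::with_seed(seed, {
    A <- matrix(rnorm(n * n), n)
    crossprod(A) / n + diag(n)
  })
}
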