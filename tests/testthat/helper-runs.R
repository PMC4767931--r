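# Shared heavy training runs, computed once per test session and reused by
# the acceptance blocks. Scales (epochs, seed counts) are the package's
# test-time study sizes; the full-scale runs live in scripts/acceptance.R.

.run_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .run_cache)) {
    assign(key, force(expr), envir = .run_cache)
  }
  get(key, envir = .run_cache)
}

# five paired synchrony replicates (bars, z = 1, epsilon 0 vs 1)
synchrony_replicates <- function(seeds = 1:5, epochs = 80) {
  cached("synchrony", lapply(seeds, function(s) {
    synchrony_experiment(seed = s, epochs = epochs)
  }))
}

# projective-field sweeps over several seeds
connectivity_replicates <- function(seeds = 1:5, epochs = 50) {
  cached("zsweep", lapply(seeds, function(s) {
    connectivity_sweep(seed = s, epochs = epochs)
  }))
}

# temporal-ratio sweeps over several seeds
temporal_replicates <- function(seeds = 1:3, epochs = 50) {
  cached("trsweep", lapply(seeds, function(s) {
    temporal_sweep(seed = s, epochs = epochs)
  }))
}
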