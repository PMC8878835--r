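# Shared fixtures, built in code.

# noiseless Gaussian ion trace on a uniform grid
gaussian_trace <- function(A = 1e4, mu = 100, sigma = 5, dt = 0.5,
                           span = 12, baseline = 0) {
  rt <- seq(mu - span * sigma, mu + span * sigma, by = dt)
  ion_trace(rt, baseline + A * exp(-(rt - mu)^2 / (2 * sigma^2)))
}

# a raw run holding one centroid channel per supplied intensity matrix column
run_from_matrix <- function(rt, mz, intens) {
  spectra <- lapply(seq_along(rt), function(i)
    cbind(mz = mz, intensity = intens[i, , drop = TRUE]))
  raw_run(rt, spectra)
}

smooth_gauss <- function(trace, win = 9) {
  smooth_trace(trace, smoother_config(), window = win)
}

# small benchmark shared by the slower integration tests (built once)
bench_cache <- local({
  env <- new.env()
  function(n_true = 40, n_false = 40, seed = 42) {
    key <- paste(n_true, n_false, seed, sep = "_")
    if (is.null(env[[key]]))
      env[[key]] <- gen_benchmark(n_true = n_true, n_false = n_false,
                                  seed = seed)
    env[[key]]
  }
})
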