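# Shared fixtures: compact simulation configurations that keep the suite
# fast while preserving the generative structure (all analysis bands stay
# below the Nyquist frequency at 128 samples/s).

tiny_sim <- function(n_subjects = 4, n_trials = 40, seed = 101, ...) {
  sim_config(n_subjects = n_subjects, n_trials_per_task = n_trials,
             srate = 128, seed = seed, ...)
}

tiny_analysis <- function(n_perm = 500, seed = 1) {
  analysis_config(n_permutations = n_perm, rng_seed = seed)
}

# One cached subject reused by several spectral/connectivity tests.
cached_subject <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- simulate_subject(tiny_sim(), 101)
    val
  }
})
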