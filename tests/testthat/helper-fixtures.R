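# Shared fixtures: all generated in code, no files.

# tiny deterministic SpectraSet
tiny_set <- function(n = 6L, p = 5L, seed = 42L) {
  set.seed(seed)
  spectra_set(matrix(runif(n * p), n, p),
              seq(1000, 1400, length.out = p),
              seq(0, 1, length.out = n),
              rep(c("corn_flour", "wheat_bran"), length.out = n))
}

# small noiseless simulated series (single adulterant)
noiseless_series <- function(levels = seq(0, 1, by = 0.1), reps = 2L) {
  simulate_dataset(mixture_design(levels = levels, adulterants = "corn_flour",
                                  replicates_per_level = reps),
                   noise_model(0, 0, 0, seed = 1L),
                   default_grid(41L))
}

# planted-signal regression data: only `k_info` of p columns carry signal
planted_signal_set <- function(n = 40L, p = 60L, k_info = 10L, seed = 1L,
                               noise_sd = 0.05) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  beta <- numeric(p)
  info <- seq_len(k_info)
  beta[info] <- runif(k_info, 0.5, 1)
  y_raw <- drop(X %*% beta) + rnorm(n, 0, noise_sd)
  y <- (y_raw - min(y_raw)) / diff(range(y_raw))   # into [0,1]
  list(set = spectra_set(X, seq(1000, 1000 + p - 1), y, rep("corn_flour", n)),
       informative = info)
}
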