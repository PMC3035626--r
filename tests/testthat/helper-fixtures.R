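# Small in-code fixtures and independent oracles shared across tests.

# Hand-built dataset: 2 units, 4 trials, 2 stimuli, TD = 200 ms.
tiny_dataset <- function() {
  spike_dataset(
    trials = list(
      spike_trial(1, "s1", list(c(10, 50, 120), c(30))),
      spike_trial(2, "s1", list(c(5, 60), numeric(0))),
      spike_trial(3, "s2", list(c(100, 150), c(20, 25, 180))),
      spike_trial(4, "s2", list(numeric(0), c(90)))
    ),
    n_units = 2, stimulus_set = c("s1", "s2"), trial_duration_ms = 200
  )
}

# Random dataset with Poisson trains, for property-style checks.
random_dataset <- function(seed, n_units = 3, n_trials = 6, TD = 300,
                           rate_hz = 25, stimuli = c("a", "b")) {
  set.seed(seed)
  trials <- lapply(seq_len(n_trials), function(k) {
    spikes <- lapply(seq_len(n_units), function(u) {
      n <- rpois(1, rate_hz * TD / 1000)
      sort(runif(n, 0, TD))
    })
    spike_trial(k, stimuli[((k - 1) %% length(stimuli)) + 1], spikes)
  })
  spike_dataset(trials, n_units, stimuli, TD)
}

# Brute-force exponential convolution: direct O(samples x spikes) sum.
conv_brute <- function(spike_times, tau_ms, TD, dt_ms = 1) {
  tt <- seq(0, by = dt_ms, length.out = ceiling(TD / dt_ms))
  vapply(tt, function(t) {
    s <- spike_times[spike_times <= t]
    sum(exp(-(t - s) / tau_ms))
  }, numeric(1))
}

# Exhaustive BMU scan (R-side oracle, lowest index on ties).
bmu_scan <- function(mv, v) {
  d2 <- rowSums(sweep(mv, 2, v)^2)
  which.min(d2) - 1L
}

# All spikes of a dataset as one long vector (for conservation checks).
all_spikes <- function(ds) {
  unlist(lapply(ds$trials, function(tr) tr$spikes), use.names = FALSE)
}

per_trial_unit_counts <- function(ds) {
  lapply(ds$trials, function(tr) lengths(tr$spikes))
}

# BMU id for every row, via the exported single-vector search.
bmu_batch_ids <- function(map, x) {
  vapply(seq_len(nrow(x)), function(r) find_bmu(map, x[r, ])$id, integer(1))
}

# Tiny trained map on fixed vectors, reused by assignment/decoding tests.
small_map <- function(seed = 42, n_dim = 3, N = 4) {
  set.seed(seed)
  x <- matrix(runif(200 * n_dim), ncol = n_dim)
  train_som(x, som_config(N = N, M = 2000, seed = seed))
}
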