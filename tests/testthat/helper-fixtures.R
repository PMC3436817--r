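# Shared fixtures. Heavy objects (cross-validation runs) are memoised per
# test session so several test files can share one computation.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# random profile: one-hot costs plus uniform jitter, seeded by caller
random_profile <- function(id, len, jitter = 1) {
  s <- paste(sample(aa_alphabet(), len, replace = TRUE), collapse = "")
  sequence_profile(id, s,
                   one_hot_costs(s) +
                     matrix(stats::runif(len * 20, 0, jitter), len, 20))
}

# profile with explicitly chosen cost rows (list of named vectors; any
# residue not named gets `default`)
costs_from_rows <- function(rows, default = 10) {
  m <- matrix(default, nrow = length(rows), ncol = 20,
              dimnames = list(NULL, aa_alphabet()))
  for (i in seq_along(rows)) m[i, names(rows[[i]])] <- rows[[i]]
  m
}

# independent brute-force Gram oracle: pairwise profile_kernel() calls
brute_gram <- function(profiles, params) {
  n <- length(profiles)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in i:n) {
    K[i, j] <- K[j, i] <- profile_kernel(profiles[[i]], profiles[[j]], params)
  }
  K
}

bacteria_topology <- function() memo("topo_bac", default_topology("bacteria"))

# the study-condition bacterial set: 6 classes x 50, clean profiles,
# k = motif length = 5
strong_bacteria_data <- function() {
  memo("bac_data", generate_dataset(synthetic_spec(
    bacteria_topology(), n_per_class = 50, seq_length = 120,
    profile_noise = 0, seed = 101)))
}

strong_bacteria_cv <- function() {
  memo("bac_cv", suppressMessages(cross_validate(
    strong_bacteria_data(), bacteria_topology(),
    kernel_params(k = 5, sigma = 7.5), eval_config(seed = 42))))
}

shuffled_bacteria_cv <- function() {
  memo("bac_cv_shuffled", suppressMessages(cross_validate(
    shuffle_labels(strong_bacteria_data(), seed = 7), bacteria_topology(),
    kernel_params(k = 5, sigma = 7.5), eval_config(seed = 42))))
}

# a noisier set whose reliability indices actually spread out
noisy_bacteria_cv <- function(noise = 2.5) {
  memo(paste0("bac_cv_noise_", noise), suppressMessages(cross_validate(
    generate_dataset(synthetic_spec(
      bacteria_topology(), n_per_class = 20, seq_length = 100,
      profile_noise = noise, seed = 131)),
    bacteria_topology(), kernel_params(k = 5, sigma = 7.5),
    eval_config(seed = 19, min_class_size_report = 10))))
}

# N-terminal-signal set and its fragment benchmark
nterm_fragment_benchmark <- function() {
  memo("frag_bench", {
    topo <- bacteria_topology()
    d <- generate_dataset(synthetic_spec(
      topo, n_per_class = 30, seq_length = 120, profile_noise = 0,
      motif_placement = "nterm", seed = 171))
    model <- train_tree(d, topo, kernel_params(k = 5, sigma = 7.5),
                        seed = 3)
    suppressWarnings(fragment_benchmark(model, d, seed = 5))
  })
}

# small trained archaea model reused by predictor tests
small_archaea_model <- function() {
  memo("arch_model", {
    topo <- default_topology("archaea")
    d <- generate_dataset(synthetic_spec(
      topo, n_per_class = 10, seq_length = 60, profile_noise = 0,
      seed = 23))
    list(model = train_tree(d, topo, kernel_params(k = 5, sigma = 7.5),
                            seed = 4),
         data = d)
  })
}
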