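# Shared fixtures: tiny deterministic graphs and series built in code.

two_region_chain <- function(weight = 0.8) {
  A <- matrix(0, 2, 2)
  A[1, 2] <- weight
  ground_truth_network(A)
}

random_graph_matrix <- function(v, seed) {
  set.seed(seed)
  A <- matrix(rnorm(v * v), v, v)
  diag(A) <- 0
  A
}

small_group_dataset <- function(n_per_class = 8, v = 10, seed = 1) {
  make_group_dataset(n_per_class, v, n_perturbed_edges = 4, effect_size = 0.8,
                     noise_sd = 0.1, seed = seed)
}
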