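# Independent oracles used to validate the implementation.  These stay
# deliberately naive: Floyd-Warshall instead of BFS, explicit subgraph
# materialization, direct complex arithmetic for PDC.

# min-plus Floyd-Warshall on a binary adjacency (adj[i, j] = 1: edge j -> i);
# returns D[s, t] = directed distance s -> t
fw_distances <- function(adj) {
  d <- nrow(adj)
  D <- matrix(Inf, d, d)
  D[t(adj) == 1] <- 1          # D[s, t]: edge s -> t means adj[t, s] == 1
  diag(D) <- 0
  for (k in seq_len(d)) {
    D <- pmin(D, outer(D[, k], D[k, ], "+"))
  }
  D
}

oracle_global_efficiency <- function(adj) {
  d <- nrow(adj)
  if (d < 2) return(0)
  D <- fw_distances(adj)
  mean(1 / D[row(D) != col(D)])
}

oracle_local_efficiency <- function(adj) {
  d <- nrow(adj)
  vapply(seq_len(d), function(i) {
    nb <- which((adj[i, ] | adj[, i]) & seq_len(d) != i)
    if (length(nb) < 2) return(0)
    oracle_global_efficiency(adj[nb, nb, drop = FALSE])
  }, numeric(1))
}

# PDC by direct complex arithmetic, looping over entries
oracle_pdc <- function(A, f, fs) {
  d <- dim(A)[1]
  p <- dim(A)[3]
  abar <- diag(d) + 0i
  for (r in seq_len(p)) {
    abar <- abar - A[, , r] * exp(-1i * 2 * pi * f * r / fs)
  }
  out <- matrix(0, d, d)
  for (j in seq_len(d)) {
    nrm <- sqrt(sum(Mod(abar[, j])^2))
    for (i in seq_len(d)) out[i, j] <- Mod(abar[i, j]) / nrm
  }
  out
}

random_adjacency <- function(d, p_edge = 0.3) {
  adj <- matrix(rbinom(d * d, 1, p_edge), d, d)
  diag(adj) <- 0
  adj
}

# small sensor recording driven by a known source model, reused across tests
make_test_recording <- function(n_samples = 4000, snr = 5, seed = 42,
                                n_locations = 30) {
  lay <- helmet_layout(n_locations)
  net <- generate_source_network(4, 5, "high", seed = seed)
  model <- build_mvar_from_network(net, 2, 0.5, seed = seed + 1)
  src <- simulate_mvar(model, n_samples, seed = seed + 2)
  gain <- make_gain_matrix(2 * n_locations, 4, lay$positions,
                           spread = 0.02, seed = seed + 3)
  rec <- project_and_add_noise(src, gain, snr, seed = seed + 4, layout = lay)
  list(recording = rec, layout = lay, network = net, model = model)
}
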