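# Small constructors and independent brute-force oracles used across the
# suite. The oracles work in the spin basis through energy() only, so they
# share no code path with the gauge-enumeration and heuristic routines
# they are used to check.

net_from_edges <- function(n, from, to, sign) {
  signed_network(paste0("v", seq_len(n)),
                 data.frame(from = from, to = to, sign = sign))
}

triangle <- function(signs = c(1, 1, 1)) {
  net_from_edges(3, c(1, 2, 1), c(2, 3, 3), signs)
}

path_net <- function(n, signs = rep(1, n - 1)) {
  net_from_edges(n, seq_len(n - 1), seq_len(n - 1) + 1, signs)
}

star_net <- function(n_leaves, signs = rep(1, n_leaves)) {
  net_from_edges(n_leaves + 1, rep(1, n_leaves), seq_len(n_leaves) + 1, signs)
}

k4_net <- function(signs = rep(1, 6)) {
  net_from_edges(4, c(1, 1, 1, 2, 2, 3), c(2, 3, 4, 3, 4, 4), signs)
}

yeast_symmetrized <- function() symmetrize(yeast_cell_cycle_network())$network

# seeded random signed graph at roughly the requested mean degree
random_test_net <- function(n, mean_deg, neg_fraction, seed) {
  m <- max(1L, round(n * mean_deg / 2))
  m <- min(m, n * (n - 1) / 2)
  random_signed_graph(generator_config(n, m, neg_fraction = neg_fraction,
                                       seed = seed))
}

# all 2^n spin states as rows (+1/-1)
all_spin_states <- function(n) {
  as.matrix(expand.grid(rep(list(c(-1L, 1L)), n)))
}

# exhaustive ground-state search in the spin basis (independent oracle)
brute_ground <- function(net) {
  S <- all_spin_states(n_nodes(net))
  hs <- apply(S, 1, function(s) energy(net, s))
  h_min <- min(hs)
  list(h_min = h_min, energies = hs,
       states = S[hs == h_min, , drop = FALSE])
}

# exact frustration index via the spin-basis oracle: h_min = 2*delta - m
brute_delta <- function(net) {
  (brute_ground(net)$h_min + n_edges(net)) / 2
}

expect_same_up_to_component_flip <- function(net, gauge, reference) {
  comp <- network_components(net)
  for (ci in seq_len(comp$count)) {
    idx <- comp$membership == ci
    agree <- gauge[idx] * reference[idx]
    expect_true(all(agree == 1L) || all(agree == -1L))
  }
}
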