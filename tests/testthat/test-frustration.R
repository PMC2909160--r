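test_that("energy counts satisfied and frustrated edges", {
  expect_equal(energy(triangle(c(1, 1, 1)), c(1, 1, 1)), -3)
  expect_equal(energy(net_from_edges(2, 1, 2, 1), c(1, -1)), 1)
  # best of the 8 states of a frustrated triangle
  expect_equal(brute_ground(triangle(c(-1, 1, 1)))$h_min, -1)
  # symmetry h(s) = h(-s)
  r <- random_test_net(9, 4, 0.4, seed = 2)
  set.seed(2)
  s <- sample(c(-1L, 1L), 9, replace = TRUE)
  expect_equal(energy(r, s), energy(r, -s))
  expect_error(energy(r, s[-1]), "length")
})

test_that("exact_frustration matches the spin-basis oracle and known cases", {
  expect_equal(exact_frustration(path_net(5, c(1, -1, 1, 1))), 0L) # trees absorb signs
  expect_equal(exact_frustration(triangle(c(-1, 1, 1))), 1L)
  expect_equal(exact_frustration(yeast_symmetrized()), 4L)
  for (seed in 1:15) {
    r <- random_test_net(10, 4, 0.3, seed = 200 + seed)
    expect_equal(exact_frustration(r), brute_delta(r))
  }
  big <- random_test_net(30, 3, 0.3, seed = 1)
  expect_error(exact_frustration(big, max_component_size = 10),
               "enumeration guard")
})

test_that("heuristic minimization attains the exact index on small graphs", {
  exact_hits <- 0L
  for (seed in 1:20) {
    r <- random_test_net(8 + (seed %% 5), 4, 0.3, seed = 300 + seed)
    fr <- minimize_frustration(r, restarts = 50, seed = 0)
    ex <- exact_frustration(r)
    expect_gte(fr$delta_up, ex)        # never undercuts the true index
    exact_hits <- exact_hits + (fr$delta_up == ex)
    # ground state energy identity in the original basis
    expect_equal(energy(r, fr$ground_state), 2 * fr$delta_up - n_edges(r))
    expect_equal(fr$ground_energy, 2 * fr$delta_up - n_edges(r))
  }
  expect_gte(exact_hits, 19L)
  # determinism for a fixed seed
  r <- random_test_net(20, 4, 0.4, seed = 11)
  expect_identical(minimize_frustration(r, restarts = 10, seed = 4),
                   minimize_frustration(r, restarts = 10, seed = 4))
})

test_that("balanced networks are solved exactly and recover the hidden gauge", {
  bg <- balanced_graph(120, 360, seed = 9)
  fr <- minimize_frustration(bg$network, restarts = 5, seed = 0)
  expect_equal(fr$delta_up, 0L)
  expect_true(fr$balanced)
  expect_same_up_to_component_flip(bg$network, fr$gauge, bg$hidden_gauge)
})

test_that("bound ordering: packing bound <= delta <= delta_up <= delta_max", {
  expect_equal(cycle_packing_lower_bound(balanced_graph(20, 40, 1)$network), 0L)
  # two vertex-disjoint frustrated triangles
  two_tri <- net_from_edges(6, c(1, 2, 1, 4, 5, 4), c(2, 3, 3, 5, 6, 6),
                            c(-1, 1, 1, -1, 1, 1))
  expect_equal(cycle_packing_lower_bound(two_tri), 2L)
  expect_equal(delta_max_bound(path_net(6)), 0L)
  expect_equal(delta_max_bound(triangle()), 1L)
  for (seed in 1:20) {
    r <- random_test_net(11, 4.5, 0.35, seed = 400 + seed)
    lo <- cycle_packing_lower_bound(r)
    ex <- exact_frustration(r)
    up <- minimize_frustration(r, restarts = 30, seed = 1)$delta_up
    expect_lte(lo, ex)
    expect_lte(ex, up)
    expect_lte(up, delta_max_bound(r))
  }
})

test_that("Z-score orientation: positive Z means less frustrated than the null", {
  z1 <- frustration_z_score(41, 116.67, 5.83)
  expect_equal(round(z1$z_score, 2), 12.98)
  z2 <- frustration_z_score(1017, 1006.9, 12.73)
  expect_equal(round(z2$z_score, 2), -0.79)
  expect_equal(frustration_z_score(10, 10, 2)$z_score, 0)
  expect_error(frustration_z_score(1, 2, 0), "degenerate")
})

test_that("sign-reshuffling null model is seeded and rejects degenerate inputs", {
  r <- random_test_net(14, 4, 0.35, seed = 17)
  nm1 <- null_model(r, replicates = 30, seed = 5, restarts = 10)
  nm2 <- null_model(r, replicates = 30, seed = 5, restarts = 10)
  expect_identical(nm1$null_deltas, nm2$null_deltas)
  expect_gte(nm1$delta_null_sd, 0)
  expect_equal(nm1$z_score,
               (nm1$delta_null_mean - nm1$delta_up) / nm1$delta_null_sd)
  expect_error(null_model(triangle(c(1, 1, 1)), replicates = 10),
               "degenerate")
})

test_that("sign packing flags concentrated hubs and is calibrated under the binomial null", {
  # one hub holding every negative edge among many positive spokes
  hub <- net_from_edges(22, c(rep(1, 6), rep(8, 14)),
                        c(2:7, 9:22), c(rep(-1, 6), rep(1, 14)))
  sp <- sign_packing(hub, replicates = 100, seed = 1)
  hub_row <- sp$nodes[sp$nodes$node == "v1", ]
  expect_true(hub_row$significant)
  expect_equal(hub_row$direction, "negative-enriched")

  # i.i.d. binomial signs: network Z stays within +/-3 (tested where the
  # significant-node count is large enough for the normal approximation)
  zs <- vapply(1:8, function(seed) {
    r <- random_test_net(400, 8, 0.3, seed = 500 + seed)
    sign_packing(r, replicates = 300, seed = seed)$z_score
  }, numeric(1))
  expect_true(all(abs(zs) <= 3))
})

test_that("maximally packed signs lower the frustration relative to the binomial twin", {
  d_skew <- d_iid <- numeric(6)
  for (seed in 1:6) {
    cfg_iid <- generator_config(40, 110, neg_fraction = 0.3,
                                sign_packing_skew = 0, seed = 600 + seed)
    cfg_skew <- generator_config(40, 110, neg_fraction = 0.3,
                                 sign_packing_skew = 1, seed = 600 + seed)
    d_iid[seed] <- minimize_frustration(random_signed_graph(cfg_iid),
                                        restarts = 20, seed = 1)$delta_up
    d_skew[seed] <- minimize_frustration(random_signed_graph(cfg_skew),
                                         restarts = 20, seed = 1)$delta_up
  }
  expect_lt(mean(d_skew), mean(d_iid))
})
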