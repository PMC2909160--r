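test_that("is_local_minimum matches the exhaustive definition", {
  bal <- balanced_graph(8, 14, seed = 2)
  expect_true(is_local_minimum(bal$network, bal$hidden_gauge))

  p <- path_net(5)
  s <- rep(1L, 5); s[3] <- -1L              # interior flip of an aligned path
  expect_false(is_local_minimum(p, s))

  r <- random_test_net(8, 4, 0.4, seed = 41)
  S <- all_spin_states(8)
  for (row in seq_len(nrow(S))) {
    s <- S[row, ]
    h <- energy(r, s)
    is_min <- TRUE
    for (i in 1:8) {
      s2 <- s; s2[i] <- -s2[i]
      if (energy(r, s2) < h) { is_min <- FALSE; break }
    }
    expect_identical(is_local_minimum(r, s), is_min)
  }
})

test_that("minima census finds the global-flip pair of a dense balanced graph", {
  # complete balanced graph: strict-descent fixed points collapse to the
  # hidden ground state and its global flip (sparser balanced graphs can
  # hold additional, genuinely local, minima)
  bal <- balanced_graph(12, 66, seed = 5)
  cen <- collect_minima(bal$network, n_starts = 300, seed = 1)
  expect_equal(length(cen$energy), 2L)
  expect_true(all(cen$label == "global"))
  expect_equal(cen$global_energy, -n_edges(bal$network))
  d <- pairwise_minima_distances(cen, "global-global")
  expect_equal(d$distances, 1)              # s and -s
  expect_equal(pairwise_minima_distances(cen, "global-global",
                                         fold_symmetry = TRUE)$distances, 0)
  expect_length(pairwise_minima_distances(cen, "local-local")$distances, 0)
})

test_that("the frustrated triangle has six degenerate minimum states", {
  cen <- collect_minima(triangle(c(-1, 1, 1)), n_starts = 400, seed = 2)
  expect_equal(length(cen$energy), 6L)
  expect_true(all(cen$energy == -1))
  expect_true(all(cen$label == "global"))
  expect_true(all(apply(cen$states, 1,
                        function(s) is_local_minimum(triangle(c(-1, 1, 1)), s))))
})

test_that("census global energy matches exact enumeration on random graphs", {
  for (seed in 1:8) {
    r <- random_test_net(10, 4, 0.35, seed = 900 + seed)
    cen <- collect_minima(r, n_starts = 500, seed = seed)
    expect_equal(cen$global_energy,
                 2 * exact_frustration(r) - n_edges(r))
    expect_true(all(apply(cen$states, 1, function(s) is_local_minimum(r, s))))
    # gauge covariance: energies of the census are preserved under a gauge
    set.seed(seed)
    g <- sample(c(-1L, 1L), 10, replace = TRUE)
    ceng <- collect_minima(apply_gauge(r, g), n_starts = 500, seed = seed)
    expect_equal(sort(unique(ceng$energy)), sort(unique(cen$energy)))
  }
})

test_that("census recovers every enumerated local minimum with many starts", {
  r <- random_test_net(8, 4, 0.4, seed = 77)
  S <- all_spin_states(8)
  truth <- S[apply(S, 1, function(s) is_local_minimum(r, s)), , drop = FALSE]
  cen <- collect_minima(r, n_starts = 3000, seed = 3)
  found <- apply(cen$states, 1, paste, collapse = ",")
  expect_setequal(found, apply(truth, 1, paste, collapse = ","))
})

test_that("interminimum trajectories flip exactly the differing spins", {
  edge <- net_from_edges(2, 1, 2, 1)
  tr <- interminimum_trajectory(edge, c(1, 1), c(-1, -1), seed = 1)
  expect_equal(nrow(tr), 3L)
  expect_equal(tr$energy, c(-1, 1, -1))     # forced barrier crossing
  expect_equal(tr$distance, c(0, 0.5, 1))

  same <- interminimum_trajectory(edge, c(1, 1), c(1, 1))
  expect_equal(nrow(same), 1L)
  expect_equal(same$step, 0L)

  for (case in 1:25) {
    r <- random_test_net(9, 4, 0.4, seed = 1000 + case)
    set.seed(case)
    a <- sample(c(-1L, 1L), 9, replace = TRUE)
    b <- sample(c(-1L, 1L), 9, replace = TRUE)
    tr <- interminimum_trajectory(r, a, b, seed = case)
    expect_equal(nrow(tr) - 1L, sum(a != b))
    expect_equal(tr$energy[1], energy(r, a))
    expect_equal(tr$energy[nrow(tr)], energy(r, b))
    expect_gte(max(tr$energy), max(tr$energy[1], tr$energy[nrow(tr)]))
    # consecutive states differ by exactly one flip: distance steps by 1/n
    expect_equal(diff(tr$distance), rep(1 / 9, nrow(tr) - 1L))
  }
})

test_that("gradient profile is nonnegative at the first step and matches K4", {
  k4 <- k4_net()
  gr <- average_gradient_profile(k4, rep(1L, 4), n_traj = 200, horizon = 4,
                                 seed = 1)
  # closed form: flipping into an aligned set of size (4 - d + 1) costs
  # 2 * (aligned neighbors - anti neighbors)
  expect_equal(gr$mean_increment, c(6, 2, -2, -6))
  expect_equal(gr$se, rep(0, 4))            # deterministic increments on K4

  for (seed in 1:5) {
    r <- random_test_net(12, 4, 0.35, seed = 1100 + seed)
    cen <- collect_minima(r, n_starts = 200, seed = seed)
    gmin <- cen$states[which(cen$label == "global")[1], ]
    gr <- average_gradient_profile(r, gmin, n_traj = 300, horizon = 6,
                                   seed = seed)
    expect_gte(gr$mean_increment[1], 0)     # definition of a local minimum
  }
  expect_warning(
    average_gradient_profile(k4, rep(1L, 4), n_traj = 10, horizon = 9,
                             seed = 1),
    "clipped")
})

test_that("funneled balanced landscapes have higher gradient peaks than frustrated ones", {
  peaks <- function(net, start, seed) {
    max(average_gradient_profile(net, start, n_traj = 300,
                                 horizon = n_nodes(net), seed = seed)$mean_increment)
  }
  wins <- 0L
  for (seed in 1:6) {
    bal <- balanced_graph(14, 42, seed = 1200 + seed)
    cfg <- generator_config(14, 42, neg_fraction = 0.5, triangle_boost = 0.5,
                            seed = 1200 + seed)
    fru <- random_signed_graph(cfg)
    fr <- minimize_frustration(fru, restarts = 30, seed = 1)
    wins <- wins + (peaks(bal$network, bal$hidden_gauge, seed) >
                      peaks(fru, fr$ground_state, seed))
  }
  expect_gte(wins, 5L)
})
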