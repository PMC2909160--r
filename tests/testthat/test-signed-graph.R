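write_lines_tmp <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("edge-list parsing handles dialects, headers and sign tokens", {
  net <- read_signed_edge_list(write_lines_tmp(c("a\tb\t+", "b\tc\t-")),
                               directed = FALSE)
  expect_equal(n_nodes(net), 3L)
  expect_equal(n_edges(net), 2L)
  expect_equal(n_negative_edges(net), 1L)
  expect_equal(net$nodes, c("a", "b", "c"))  # first-appearance order

  csv <- read_signed_edge_list(
    write_lines_tmp(c("source,target,sign", "a,b,+1", "b,c,-1", "c,d,activation")))
  expect_equal(n_edges(csv), 3L)
  expect_equal(csv$edges$sign, c(1L, -1L, 1L))

  sif <- read_signed_edge_list(
    write_lines_tmp(c("a\tactivates\tb", "b\tinhibits\tc")), directed = TRUE)
  expect_equal(sif$edges$sign, c(1L, -1L))
  expect_equal(sif$nodes, c("a", "b", "c"))
})

test_that("degenerate and malformed edge lists are handled", {
  empty <- read_signed_edge_list(write_lines_tmp(character(0)), directed = FALSE)
  expect_equal(n_nodes(empty), 0L)
  expect_equal(n_edges(empty), 0L)

  expect_error(read_signed_edge_list(write_lines_tmp("a\tb\tmaybe")),
               "line 1.*unparsable")
  expect_error(
    read_signed_edge_list(write_lines_tmp(c("a\tb\t+", "a\tb\t-"))),
    "line 2.*opposite sign")
  # equal-sign duplicates are deduplicated silently
  dup <- read_signed_edge_list(write_lines_tmp(c("a\tb\t+", "a\tb\t+")))
  expect_equal(n_edges(dup), 1L)
})

test_that("symmetrize keeps compatible pairs and drops conflicting ones", {
  d <- directed_signed_network(c("a", "b"),
                               data.frame(from = c(1, 2), to = c(2, 1),
                                          sign = c(1, 1)))
  s <- symmetrize(d)
  expect_equal(n_edges(s$network), 1L)
  expect_equal(s$conflicts, 0L)

  d2 <- directed_signed_network(c("a", "b"),
                                data.frame(from = c(1, 2), to = c(2, 1),
                                           sign = c(1, -1)))
  s2 <- symmetrize(d2)
  expect_equal(n_edges(s2$network), 0L)
  expect_equal(s2$conflicts, 1L)

  # symmetrizing an already-symmetric pattern is idempotent, no conflicts
  und <- random_test_net(12, 4, 0.3, seed = 7)
  dd <- directed_signed_network(und$nodes,
                                data.frame(from = c(und$edges$from, und$edges$to),
                                           to = c(und$edges$to, und$edges$from),
                                           sign = rep(und$edges$sign, 2)))
  s3 <- symmetrize(dd)
  expect_equal(s3$conflicts, 0L)
  expect_equal(s3$network$edges, und$edges)
})

test_that("yeast cell-cycle symmetrization matches the fixture's documented counts", {
  y <- yeast_cell_cycle_network()
  expect_equal(n_nodes(y), 11L)
  s <- symmetrize(y)
  expect_equal(s$conflicts, 1L)
  expect_equal(n_edges(s$network), 23L)
  expect_equal(n_negative_edges(s$network), 10L)
})

test_that("gauge transformations move signs but preserve cycle structure", {
  net <- net_from_edges(2, 1, 2, -1)
  flipped <- apply_gauge(net, c(-1, 1))
  expect_equal(flipped$edges$sign, 1L)
  expect_equal(apply_gauge(net, c(1, 1))$edges, net$edges)  # identity
  expect_error(apply_gauge(net, c(1, 1, 1)), "length")

  for (seed in 1:5) {
    r <- random_test_net(10, 4, 0.4, seed = seed)
    set.seed(seed)
    g <- sample(c(-1L, 1L), n_nodes(r), replace = TRUE)
    # involution: applying the same gauge twice restores the network
    expect_equal(apply_gauge(apply_gauge(r, g), g)$edges, r$edges)
    # triangle signs (products around every 3-cycle) are invariant
    gr <- apply_gauge(r, g)
    J0 <- adjacency_matrix(r); J1 <- adjacency_matrix(gr)
    n <- n_nodes(r)
    for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
      expect_identical(J0[i, j] * J0[j, k] * J0[i, k],
                       J1[i, j] * J1[j, k] * J1[i, k])
    }
    # and so is the exact frustration index
    expect_identical(exact_frustration(r), exact_frustration(gr))
  }
})

test_that("gauge on the yeast network reaches the 4-negative-edge optimum", {
  s <- yeast_symmetrized()
  g <- rep(1L, 11)
  g[match(c("Cln1_2", "Clb5_6", "Clb1_2"), s$nodes)] <- -1L
  expect_equal(n_negative_edges(apply_gauge(s, g)), 4L)
})

test_that("balance_test agrees with the spin-basis oracle and returns witnesses", {
  expect_true(balance_test(triangle(c(1, 1, 1)))$balanced)
  bt <- balance_test(triangle(c(-1, 1, 1)))
  expect_false(bt$balanced)
  expect_setequal(bt$witness_cycle, 1:3)

  for (seed in 1:12) {
    r <- random_test_net(8, 3.5, 0.3, seed = seed)
    bt <- balance_test(r)
    expect_equal(bt$balanced, brute_delta(r) == 0)
    if (bt$balanced) {
      expect_equal(n_negative_edges(apply_gauge(r, bt$gauge)), 0L)
    } else {
      # witness cycle exists in the graph and has odd negative count
      cyc <- bt$witness_cycle
      J <- adjacency_matrix(r)
      k <- length(cyc)
      signs <- vapply(seq_len(k), function(t)
        J[cyc[t], cyc[if (t == k) 1L else t + 1L]], numeric(1))
      expect_true(all(signs != 0))
      expect_equal(prod(signs), -1)
    }
  }
})

test_that("hidden gauges of balanced constructions are recovered", {
  for (seed in 1:5) {
    bg <- balanced_graph(30, 60, seed = seed)
    bt <- balance_test(bg$network)
    expect_true(bt$balanced)
    expect_same_up_to_component_flip(bg$network, bt$gauge, bg$hidden_gauge)
  }
})

test_that("two_core prunes leaves without changing the frustration index", {
  st <- two_core(star_net(5))
  expect_equal(n_nodes(st$network), 0L)
  expect_equal(st$removed, 6L)

  tri_pendant <- net_from_edges(6, c(1, 2, 1, 3, 4, 5), c(2, 3, 3, 4, 5, 6),
                                c(1, 1, -1, 1, -1, 1))
  tc <- two_core(tri_pendant)
  expect_equal(tc$removed, 3L)
  expect_setequal(tc$network$nodes, c("v1", "v2", "v3"))

  for (seed in 1:10) {
    r <- random_test_net(12, 3, 0.3, seed = 100 + seed)
    tc <- two_core(r)
    expect_identical(exact_frustration(tc$network), exact_frustration(r))
  }
})

test_that("degree_profile partitions nodes and satisfies the handshake identity", {
  k4 <- k4_net()
  p <- degree_profile(k4)
  expect_equal(p$k, 3)
  expect_equal(p$p_k, 1)
  expect_equal(p$k_pn, 3)

  neg_edge <- net_from_edges(2, 1, 2, -1)
  p2 <- degree_profile(neg_edge)
  expect_equal(p2$k, 1)
  expect_equal(p2$k_pn, -1)

  expect_equal(length(degree_profile(signed_network(character(0)))$k), 0L)

  for (seed in 1:5) {
    r <- random_test_net(40, 5, 0.3, seed = seed)
    p <- degree_profile(r)
    expect_equal(sum(p$p_k), 1)
    expect_equal(p$n * sum(p$p_k * p$k), 2 * n_edges(r))
    expect_equal(p$mean_k, sum(p$k * p$p_k))
  }
})
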