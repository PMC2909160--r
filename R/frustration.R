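# CSR view of the undirected network for the compiled kernels (0-based)
as_csr <- function(net) {
  n <- n_nodes(net)
  adj <- adjacency_list(net)
  deg <- lengths(adj$nbr)
  list(ptr = as.integer(c(0L, cumsum(deg))),
       nbr = as.integer(unlist(adj$nbr, use.names = FALSE) - 1L),
       sgn = as.integer(unlist(adj$sign, use.names = FALSE)))
}

#' Ising energy of a spin configuration
#'
#' \eqn{h(s) = -\sum_{(i,j) \in E} J_{ij} s_i s_j}, each unordered edge
#' counted once. Satisfied edges (J s s > 0) contribute -1, frustrated
#' edges +1, so h ranges over \[-m, m\] and h(s) = h(-s).
#'
#' @param net a [signed_network()].
#' @param s spin state, one +1/-1 per node.
#' @return the energy (numeric scalar).
#' @export
energy <- function(net, s) {
  s <- check_spin(net, s)
  e <- net$edges
  if (nrow(e) == 0L) return(0)
  -sum(e$sign * s[e$from] * s[e$to])
}

#' Heuristic frustration minimization over gauges
#'
#' Searches for the gauge with the fewest negative edges (the frustration
#' index upper bound delta_up). Balanced connected components are solved
#' exactly in linear time by [balance_test()]; on the remaining components
#' a seeded multi-restart simulated annealing (geometric cooling from
#' temperature 2, ratio 0.95, 200 sweeps per restart) followed by greedy
#' single-node descent is used. Deterministic for a fixed seed.
#'
#' @param net a [signed_network()].
#' @param restarts number of annealing restarts per frustrated component.
#' @param seed integer seed; `NULL` continues the current RNG stream.
#' @return object of class `frustration_result`: list with `delta_up`,
#'   `delta_low` (edge-disjoint frustrated-cycle packing bound), `gauge`,
#'   `ground_state` (= the gauge: in the gauged basis the all-up state is
#'   the candidate ground state, so s_ground = D_sigma 1), `ground_energy`
#'   (= 2 delta_up - m), `m`, and `balanced`.
#' @export
minimize_frustration <- function(net, restarts = 50L, seed = 0L) {
  stopifnot(inherits(net, "signed_network"), restarts >= 1L)
  if (!is.null(seed)) set.seed(seed)
  n <- n_nodes(net)
  m <- n_edges(net)
  gauge <- rep(1L, n)
  delta_up <- 0L
  comp <- network_components(net)
  for (ci in seq_len(comp$count)) {
    keep <- which(comp$membership == ci)
    sub <- if (comp$count == 1L) net else induced_subnetwork(net, keep)
    bt <- balance_test(sub)
    if (bt$balanced) {
      gauge[keep] <- bt$gauge
    } else {
      csr <- as_csr(sub)
      res <- cpp_anneal_gauge(csr$ptr, csr$nbr, csr$sgn,
                              as.integer(restarts), 2.0, 0.95, 200L)
      gauge[keep] <- res$gauge
      delta_up <- delta_up + res$negative
    }
  }
  delta_low <- cycle_packing_lower_bound(net)
  structure(list(delta_up = as.integer(delta_up),
                 delta_low = as.integer(min(delta_low, delta_up)),
                 gauge = gauge,
                 ground_state = gauge,
                 ground_energy = 2 * delta_up - m,
                 m = m,
                 balanced = delta_up == 0L),
            class = "frustration_result")
}

#' @export
print.frustration_result <- function(x, ...) {
  cat(sprintf("frustration_result: delta in [%d, %d] of m = %d edges; ground energy %g\n",
              x$delta_low, x$delta_up, x$m, x$ground_energy))
  invisible(x)
}

#' Exact frustration index by gauge enumeration
#'
#' Enumerates all 2^(n-1) gauge classes per connected component (the global
#' flip is fixed) and returns the minimum achievable number of negative
#' edges — the exact frustration index delta, i.e. the MAX-CUT-equivalent
#' ground-state computation. Intended for small graphs.
#'
#' @param net a [signed_network()].
#' @param max_component_size enumeration guard (default 20 nodes).
#' @return integer, the exact frustration index.
#' @export
exact_frustration <- function(net, max_component_size = 20L) {
  comp <- network_components(net)
  total <- 0L
  for (ci in seq_len(comp$count)) {
    keep <- which(comp$membership == ci)
    sub <- if (comp$count == 1L) net else induced_subnetwork(net, keep)
    nc <- n_nodes(sub)
    if (nc > max_component_size)
      stop("component with ", nc, " nodes exceeds the enumeration guard (",
           max_component_size, "); use minimize_frustration()")
    mc <- n_edges(sub)
    if (mc == 0L) next
    if (mc == nc - 1L) next  # tree component: always balanced
    e <- sub$edges
    best <- mc
    n_codes <- 2^(nc - 1L)
    chunk <- 65536L
    for (start in seq(0, n_codes - 1L, by = chunk)) {
      codes <- start:min(start + chunk - 1L, n_codes - 1L)
      S <- matrix(1, nrow = nc, ncol = length(codes))
      for (b in seq_len(nc - 1L))
        S[b + 1L, ] <- 1 - 2 * (bitwAnd(codes, bitwShiftL(1L, b - 1L)) > 0)
      sat <- colSums(e$sign * S[e$from, , drop = FALSE] *
                       S[e$to, , drop = FALSE])
      best <- min(best, (mc - max(sat)) / 2)
    }
    total <- total + best
  }
  as.integer(total)
}

#' Lower bound on the frustration index by frustrated-cycle packing
#'
#' Greedily collects edge-disjoint cycles with an odd number of negative
#' edges (each found by the sign-consistent traversal of [balance_test()],
#' then removed from the working graph). Any spin assignment must leave at
#' least one unsatisfied edge on each such cycle, and the cycles share no
#' edges, so their count is a valid lower bound on delta.
#'
#' @param net a [signed_network()].
#' @param seed accepted for interface symmetry; the traversal itself is
#'   deterministic, so the result does not depend on it.
#' @return integer lower bound (0 for balanced networks).
#' @export
cycle_packing_lower_bound <- function(net, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  count <- 0L
  work <- net
  repeat {
    bt <- balance_test(work)
    if (bt$balanced) return(count)
    count <- count + 1L
    cyc <- bt$witness_cycle
    k <- length(cyc)
    pairs <- cbind(cyc, cyc[c(2:k, 1L)])
    lo <- pmin(pairs[, 1L], pairs[, 2L]); hi <- pmax(pairs[, 1L], pairs[, 2L])
    drop_key <- paste(lo, hi)
    e <- work$edges
    keep <- !(paste(e$from, e$to) %in% drop_key)
    work <- signed_network(work$nodes, e[keep, , drop = FALSE])
  }
}

#' Topological upper bound on the frustration index
#'
#' Default bound `min(floor(m/2), m - n + c)` combining the trivial
#' half-the-edges bound with the cycle rank (a spanning forest is balanced,
#' so at most one violated edge per independent cycle is ever needed).
#' Pluggable: supply `fun(net)` to override.
#'
#' @param net a [signed_network()].
#' @param fun optional replacement bound, a function of the network.
#' @return integer upper bound delta_max.
#' @export
delta_max_bound <- function(net, fun = NULL) {
  if (!is.null(fun)) return(as.integer(fun(net)))
  m <- n_edges(net)
  n <- n_nodes(net)
  c <- network_components(net)$count
  as.integer(min(m %/% 2L, m - n + c))
}

#' Z-score of an observed frustration against a null ensemble
#'
#' Convention: `z = (null_mean - delta_up) / null_sd`, so a positive Z
#' means the network is less frustrated than its sign-reshuffled null.
#' The p-value is the normal tail on the observed side.
#'
#' @param delta_up observed frustration estimate.
#' @param null_mean,null_sd mean and standard deviation of the null
#'   frustration estimates.
#' @return list with `z_score` and `p_value`.
#' @export
frustration_z_score <- function(delta_up, null_mean, null_sd) {
  if (null_sd <= 0) stop("degenerate null (sd = 0)")
  z <- (null_mean - delta_up) / null_sd
  list(z_score = z, p_value = stats::pnorm(-abs(z)))
}

#' Sign-reshuffling null model for the frustration index
#'
#' Permutes the multiset of edge signs over the fixed edge skeleton
#' (preserving the number of positive and negative edges), re-estimates
#' delta_up with the heuristic for each replicate, and reports the Z-score
#' of the observed network against that ensemble.
#'
#' @param net a [signed_network()] with at least one edge of each sign.
#' @param replicates number of sign permutations (>= 2).
#' @param seed integer seed; `NULL` continues the current stream.
#' @param restarts annealing restarts per replicate.
#' @param delta_up observed value; computed with the same `restarts` if
#'   missing.
#' @return object of class `null_model_result`: `delta_up`,
#'   `delta_null_mean`, `delta_null_sd`, `z_score`, `p_value`,
#'   `replicates`, `seed`, `null_deltas`.
#' @export
null_model <- function(net, replicates = 1000L, seed = 0L, restarts = 10L,
                       delta_up = NULL) {
  stopifnot(inherits(net, "signed_network"), replicates >= 2L)
  m <- n_edges(net)
  n_neg <- n_negative_edges(net)
  if (n_neg == 0L || n_neg == m)
    stop("degenerate null: network needs at least one edge of each sign")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(delta_up))
    delta_up <- minimize_frustration(net, restarts = restarts, seed = NULL)$delta_up
  signs <- net$edges$sign
  deltas <- integer(replicates)
  for (r in seq_len(replicates)) {
    shuffled <- net
    shuffled$edges$sign <- sample(signs)
    deltas[r] <- minimize_frustration(shuffled, restarts = restarts,
                                      seed = NULL)$delta_up
  }
  mu <- mean(deltas); sdv <- stats::sd(deltas)
  zs <- frustration_z_score(delta_up, mu, sdv)
  structure(list(delta_up = delta_up, delta_null_mean = mu,
                 delta_null_sd = sdv, z_score = zs$z_score,
                 p_value = zs$p_value, replicates = replicates,
                 seed = seed, null_deltas = deltas),
            class = "null_model_result")
}

#' @export
print.null_model_result <- function(x, ...) {
  cat(sprintf("null_model_result: delta_up = %d vs null %.2f +/- %.2f (Z = %.2f, p = %.3g, %d replicates)\n",
              x$delta_up, x$delta_null_mean, x$delta_null_sd, x$z_score,
              x$p_value, x$replicates))
  invisible(x)
}

#' Sign-packing statistics
#'
#' Tests, per node, whether its count of negative incident edges is
#' extreme for its degree under a binomial model with the network-wide
#' negative-edge fraction (two-sided exact binomial test). The
#' network-level packing statistic is the number of nodes significant at
#' `alpha`; its Z-score is computed against sign-reshuffled replicates
#' (positive Z = more sign-packed nodes than expected).
#'
#' @param net a [signed_network()] with both edge signs present.
#' @param alpha per-node significance level.
#' @param replicates null replicates for the network-level Z.
#' @param seed integer seed; `NULL` continues the current stream.
#' @return object of class `sign_packing_result`: per-node data frame
#'   (`node`, `degree`, `negative`, `p_value`, `direction`, `significant`),
#'   `n_significant`, `null_mean`, `null_sd`, `z_score`, `p_value`.
#' @export
sign_packing <- function(net, alpha = 0.05, replicates = 1000L, seed = 0L) {
  stopifnot(inherits(net, "signed_network"))
  m <- n_edges(net)
  n_neg <- n_negative_edges(net)
  if (n_neg == 0L || n_neg == m)
    stop("degenerate null: network needs at least one edge of each sign")
  if (!is.null(seed)) set.seed(seed)
  f <- n_neg / m
  n <- n_nodes(net)
  deg <- tabulate(c(net$edges$from, net$edges$to), nbins = n)
  # two-sided exact binomial p-values, tabulated once per degree class
  # (same definition as binom.test: sum of outcome probabilities not
  # exceeding that of the observed count)
  ptab <- lapply(stats::setNames(nm = sort(unique(deg[deg > 0L]))), function(d) {
    pr <- stats::dbinom(0:d, d, f)
    vapply(pr, function(px) sum(pr[pr <= px * (1 + 1e-7)]), numeric(1))
  })
  count_significant <- function(e) {
    neg <- tabulate(c(e$from[e$sign < 0], e$to[e$sign < 0]), nbins = n)
    p <- rep(1, n)
    nz <- deg > 0L
    p[nz] <- mapply(function(d, x) ptab[[as.character(d)]][x + 1L],
                    deg[nz], neg[nz])
    list(deg = deg, neg = neg, p = p, count = sum(p <= alpha & deg > 0L))
  }
  obs <- count_significant(net$edges)
  nulls <- integer(replicates)
  e <- net$edges
  for (r in seq_len(replicates)) {
    e_r <- e
    e_r$sign <- sample(e$sign)
    nulls[r] <- count_significant(e_r)$count
  }
  mu <- mean(nulls); sdv <- stats::sd(nulls)
  z <- if (sdv > 0) (obs$count - mu) / sdv else NA_real_
  nodes <- data.frame(node = net$nodes, degree = obs$deg, negative = obs$neg,
                      p_value = obs$p,
                      direction = ifelse(obs$deg == 0L, "none",
                                         ifelse(obs$neg / pmax(obs$deg, 1L) >= f,
                                                "negative-enriched",
                                                "positive-enriched")),
                      significant = obs$p <= alpha & obs$deg > 0L)
  structure(list(nodes = nodes, n_significant = obs$count,
                 null_mean = mu, null_sd = sdv, z_score = z,
                 p_value = if (is.na(z)) NA_real_ else stats::pnorm(-abs(z)),
                 alpha = alpha, neg_fraction = f, replicates = replicates),
            class = "sign_packing_result")
}

#' @export
print.sign_packing_result <- function(x, ...) {
  cat(sprintf("sign_packing_result: %d/%d nodes significant at alpha = %g (null %.2f +/- %.2f, Z = %.2f)\n",
              x$n_significant, nrow(x$nodes), x$alpha, x$null_mean,
              x$null_sd, x$z_score))
  invisible(x)
}
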