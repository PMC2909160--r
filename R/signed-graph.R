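#' Symmetrize a directed signed network
#'
#' Collapses the directed sign pattern J_ns to the symmetric signed
#' adjacency matrix J of the underlying undirected graph. An edge pair
#' (i->j, j->i) is compatible when the product of its signs is nonnegative
#' with at least one nonzero entry; the undirected edge then carries the
#' common sign. Incompatible pairs (opposite signs) are removed and counted.
#' Self-loops are dropped: the monotonicity order relations they induce are
#' trivial.
#'
#' @param net a [directed_signed_network()].
#' @param drop_self_loops logical, drop diagonal entries (default `TRUE`).
#' @return list with `network` (a [signed_network()] on the same node set,
#'   in the same order) and `conflicts` (number of incompatible pairs
#'   removed).
#' @export
symmetrize <- function(net, drop_self_loops = TRUE) {
  stopifnot(inherits(net, "directed_signed_network"))
  e <- net$edges
  if (drop_self_loops) e <- e[e$from != e$to, , drop = FALSE]
  else if (any(e$from == e$to))
    stop("cannot symmetrize self-loops; set drop_self_loops = TRUE")
  if (nrow(e) == 0L)
    return(list(network = signed_network(net$nodes), conflicts = 0L))
  lo <- pmin(e$from, e$to); hi <- pmax(e$from, e$to)
  key <- paste(lo, hi)
  sgn <- tapply(e$sign, key, function(s) {
    if (all(s > 0)) 1L else if (all(s < 0)) -1L else NA_integer_
  })
  u <- !duplicated(key)
  s_out <- as.integer(sgn[key[u]])
  conflicts <- sum(is.na(s_out))
  ok <- !is.na(s_out)
  list(network = signed_network(net$nodes,
                                data.frame(from = lo[u][ok], to = hi[u][ok],
                                           sign = s_out[ok])),
       conflicts = conflicts)
}

#' Apply a gauge (switching) transformation
#'
#' Replaces each edge sign by \eqn{J'_{ij} = g_i J_{ij} g_j}. The topology
#' and the sign of every cycle — hence the frustration index — are
#' unchanged; only the distribution of negative edges moves.
#'
#' @param net a [signed_network()].
#' @param g gauge vector, one +1/-1 value per node.
#' @return the gauged `signed_network`.
#' @export
apply_gauge <- function(net, g) {
  g <- check_spin(net, g, "gauge vector")
  e <- net$edges
  if (nrow(e)) e$sign <- as.integer(g[e$from] * e$sign * g[e$to])
  signed_network(net$nodes, e)
}

#' Test structural balance and recover a gauge or a frustrated cycle
#'
#' A signed graph is balanced (the interaction graph of a monotone system)
#' iff some gauge makes every edge sign nonnegative, equivalently iff no
#' undirected cycle carries an odd number of negative edges. The test is a
#' sign-consistent breadth-first traversal: linear in the network size.
#'
#' @param net a [signed_network()].
#' @return list with `balanced` (logical); if balanced, `gauge` (+1/-1 per
#'   node, one arbitrary global sign per connected component) such that
#'   `apply_gauge(net, gauge)` is all-positive; otherwise `witness_cycle`,
#'   the node indices of one cycle with an odd number of negative edges.
#' @export
balance_test <- function(net) {
  n <- n_nodes(net)
  if (n == 0L) return(list(balanced = TRUE, gauge = integer(0)))
  adj <- adjacency_list(net)
  g <- integer(n)            # 0 = unvisited
  parent <- integer(n)
  for (root in seq_len(n)) {
    if (g[root] != 0L) next
    g[root] <- 1L; parent[root] <- 0L
    queue <- root
    while (length(queue)) {
      u <- queue[[1L]]; queue <- queue[-1L]
      nb <- adj$nbr[[u]]; sg <- adj$sign[[u]]
      for (k in seq_along(nb)) {
        v <- nb[k]
        want <- g[u] * sg[k]   # g_v making the edge positive
        if (g[v] == 0L) {
          g[v] <- want; parent[v] <- u; queue <- c(queue, v)
        } else if (g[v] != want) {
          return(list(balanced = FALSE,
                      witness_cycle = tree_cycle(parent, u, v)))
        }
      }
    }
  }
  list(balanced = TRUE, gauge = g)
}

# cycle through BFS-tree paths of u and v plus the edge (u, v)
tree_cycle <- function(parent, u, v) {
  path_to_root <- function(x) {
    p <- x
    while (parent[x] != 0L) { x <- parent[x]; p <- c(p, x) }
    p
  }
  pu <- path_to_root(u); pv <- path_to_root(v)
  common <- intersect(pu, pv)
  meet <- common[[1L]]  # deepest common ancestor: first shared on u's path
  c(pu[seq_len(match(meet, pu))], rev(pv[seq_len(match(meet, pv) - 1L)]))
}

#' 2-core of a signed network
#'
#' Iteratively removes nodes of degree at most one until none remain. Trees
#' are balanced, so pruning leaves changes neither the frustration index nor
#' any cycle statistic; it does shift the mean-field order threshold, which
#' is why the 2-core is analyzed separately.
#'
#' @param net a [signed_network()].
#' @return list with `network` (the 2-core, possibly empty) and `removed`
#'   (number of nodes pruned).
#' @export
two_core <- function(net) {
  n <- n_nodes(net)
  if (n == 0L) return(list(network = net, removed = 0L))
  core <- igraph::coreness(as_igraph(net))
  keep <- which(core >= 2)
  list(network = induced_subnetwork(net, keep),
       removed = n - length(keep))
}

#' Degree profile of a signed network
#'
#' Groups nodes into classes by (total) degree and records, per class, the
#' class probability and the mean difference between positive and negative
#' incident edges, k_pn. After a frustration-minimizing gauge k_pn is close
#' to k, and it is k_pn that enters the frustration-corrected mean field.
#'
#' @param net a [signed_network()].
#' @return object of class `degree_profile`: list with `k` (distinct
#'   degrees, ascending), `p_k` (class probabilities, summing to 1), `k_pn`
#'   (per-class mean positive-minus-negative degree), `mean_k`, and `n`.
#' @export
degree_profile <- function(net) {
  n <- n_nodes(net)
  if (n == 0L) {
    return(structure(list(k = numeric(0), p_k = numeric(0),
                          k_pn = numeric(0), mean_k = NaN, n = 0L),
                     class = "degree_profile"))
  }
  e <- net$edges
  deg <- tabulate(c(e$from, e$to), nbins = n)
  pn <- numeric(n)
  if (nrow(e)) {
    pos <- tabulate(c(e$from[e$sign > 0], e$to[e$sign > 0]), nbins = n)
    neg <- deg - pos
    pn <- pos - neg
  }
  ks <- sort(unique(deg))
  p_k <- as.numeric(table(factor(deg, levels = ks))) / n
  k_pn <- vapply(ks, function(k) mean(pn[deg == k]), numeric(1))
  structure(list(k = as.numeric(ks), p_k = p_k, k_pn = k_pn,
                 mean_k = sum(ks * p_k), n = n),
            class = "degree_profile")
}

#' @export
print.degree_profile <- function(x, ...) {
  cat(sprintf("degree_profile: %d nodes, %d degree classes, <k> = %.3f\n",
              x$n, length(x$k), x$mean_k))
  invisible(x)
}
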