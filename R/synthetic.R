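#' Generator configuration for random signed networks
#'
#' @param n number of nodes.
#' @param m number of edges (must leave room for the leaf nodes:
#'   `m >= n * leaf_fraction`).
#' @param degree_model `"erdos-renyi-like"` (uniform random simple graph)
#'   or `"powerlaw-configuration"` (stub-matching configuration model with
#'   self-/multi-edge rejection on a heavy-tailed degree sequence).
#' @param neg_fraction target fraction of negative (inhibitory) edges.
#' @param sign_packing_skew 0 = i.i.d. binomial signs; 1 = per-node
#'   negative propensities maximally concentrated (each node is almost
#'   purely activator or purely inhibitor), emulating the skewed sign
#'   distributions of transcriptional networks.
#' @param triangle_boost extra triadic closure: the fraction of edges
#'   rewired to close open triangles, emulating the short-cycle enrichment
#'   of stoichiometric networks.
#' @param leaf_fraction fraction of nodes attached last as degree-1
#'   pendants, emulating the tree-like parts of transcriptional networks.
#' @param powerlaw_exponent exponent of the heavy-tailed degree model.
#' @param seed integer seed.
#' @return a `generator_config` list.
#' @export
generator_config <- function(n, m,
                             degree_model = c("erdos-renyi-like",
                                              "powerlaw-configuration"),
                             neg_fraction = 0.3, sign_packing_skew = 0,
                             triangle_boost = 0, leaf_fraction = 0,
                             powerlaw_exponent = 2.5, seed = 0L) {
  degree_model <- match.arg(degree_model)
  stopifnot(n >= 1, m >= 0, neg_fraction >= 0, neg_fraction <= 1,
            sign_packing_skew >= 0, sign_packing_skew <= 1,
            triangle_boost >= 0, leaf_fraction >= 0, leaf_fraction < 1)
  if (m < n * leaf_fraction)
    stop("m must be at least n * leaf_fraction (one edge per pendant node)")
  structure(list(n = as.integer(n), m = as.integer(m),
                 degree_model = degree_model, neg_fraction = neg_fraction,
                 sign_packing_skew = sign_packing_skew,
                 triangle_boost = triangle_boost,
                 leaf_fraction = leaf_fraction,
                 powerlaw_exponent = powerlaw_exponent,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Random balanced (monotone) signed network with a hidden gauge
#'
#' Draws a uniform random simple graph, a hidden gauge sigma* uniformly,
#' and sets every edge sign to \eqn{J_{ij} = \sigma^*_i \sigma^*_j}. The
#' result is balanced by construction (frustration index 0) and
#' `apply_gauge(net, hidden_gauge)` is all-positive, so the hidden gauge is
#' a ground-truth target for gauge-recovery tests.
#'
#' @param n number of nodes.
#' @param m number of edges (at most n(n-1)/2).
#' @param seed integer seed; `NULL` continues the current stream.
#' @return list with `network` (a [signed_network()]) and `hidden_gauge`.
#' @export
balanced_graph <- function(n, m, seed = 0L) {
  if (m > n * (n - 1) / 2) stop("m exceeds the simple-graph maximum")
  if (!is.null(seed)) set.seed(seed)
  el <- igraph::as_edgelist(igraph::sample_gnm(n, m))
  sigma <- sample(c(-1L, 1L), n, replace = TRUE)
  edges <- data.frame(from = el[, 1L], to = el[, 2L],
                      sign = sigma[el[, 1L]] * sigma[el[, 2L]])
  list(network = signed_network(paste0("v", seq_len(n)), edges),
       hidden_gauge = sigma)
}

# heavy-tailed degree sequence summing to 2m, entries in [1, n-1]
powerlaw_degrees <- function(n, m, exponent) {
  w <- (seq_len(n))^(-1 / (exponent - 1))   # Zipf-like weights
  d <- pmax(1L, round(w / sum(w) * 2 * m))
  d <- pmin(d, n - 1L)
  gap <- 2L * m - sum(d)
  i <- 1L
  while (gap != 0L) {                        # distribute the remainder
    step <- sign(gap)
    if (d[i] + step >= 1L && d[i] + step <= n - 1L) {
      d[i] <- d[i] + step; gap <- gap - step
    }
    i <- if (i == n) 1L else i + 1L
  }
  sample(d)                                  # detach degree from identity
}

# stub matching with rejection of self-loops and multi-edges; topped up
# with uniform non-edges to reach exactly m
configuration_edges <- function(n, m, exponent) {
  d <- powerlaw_degrees(n, m, exponent)
  stubs <- sample(rep.int(seq_len(n), d))
  seen <- new.env(parent = emptyenv())
  from <- integer(0); to <- integer(0)
  for (k in seq_len(length(stubs) %/% 2L)) {
    a <- stubs[2L * k - 1L]; b <- stubs[2L * k]
    if (a == b) next
    key <- paste(min(a, b), max(a, b))
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    from <- c(from, min(a, b)); to <- c(to, max(a, b))
  }
  while (length(from) < m) {
    a <- sample.int(n, 1L); b <- sample.int(n, 1L)
    if (a == b) next
    key <- paste(min(a, b), max(a, b))
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    from <- c(from, min(a, b)); to <- c(to, max(a, b))
  }
  cbind(from[seq_len(m)], to[seq_len(m)])
}

#' Random signed network with tunable sign and topology structure
#'
#' Builds the topology from the configured degree model on the non-leaf
#' core, boosts triadic closure by rewiring a `triangle_boost` fraction of
#' edges onto open triads, attaches the pendant (leaf) nodes last, and
#' then assigns signs: i.i.d. Bernoulli(`neg_fraction`) at skew 0, or from
#' per-node negative propensities drawn from a symmetric two-point mixture
#' of spread `sign_packing_skew` (an edge is negative with probability
#' equal to the mean of its endpoint propensities).
#'
#' @param cfg a [generator_config()].
#' @return a [signed_network()]. Deterministic given `cfg$seed`.
#' @export
random_signed_graph <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(cfg$seed)
  n <- cfg$n; m <- cfg$m
  n_leaf <- round(n * cfg$leaf_fraction)
  n_core <- n - n_leaf
  m_core <- m - n_leaf
  if (m_core > n_core * (n_core - 1) / 2)
    stop("core edge count exceeds the simple-graph maximum")
  el <- if (cfg$degree_model == "erdos-renyi-like") {
    igraph::as_edgelist(igraph::sample_gnm(n_core, m_core))
  } else {
    configuration_edges(n_core, m_core, cfg$powerlaw_exponent)
  }
  if (cfg$triangle_boost > 0 && m_core >= 3L) {
    el <- boost_triangles(el, n_core, round(cfg$triangle_boost * m_core))
  }
  # pendant nodes, one uniform anchor in the core each
  if (n_leaf > 0L) {
    anchors <- sample.int(n_core, n_leaf, replace = TRUE)
    el <- rbind(el, cbind(anchors, n_core + seq_len(n_leaf)))
  }
  lo <- pmin(el[, 1L], el[, 2L]); hi <- pmax(el[, 1L], el[, 2L])
  signs <- draw_signs(lo, hi, n, cfg$neg_fraction, cfg$sign_packing_skew)
  signed_network(paste0("v", seq_len(n)),
                 data.frame(from = lo, to = hi, sign = signs))
}

# rewire up to n_moves edges so that they close open triads
boost_triangles <- function(el, n, n_moves) {
  seen <- new.env(parent = emptyenv())
  for (r in seq_len(nrow(el)))
    seen[[paste(el[r, 1L], el[r, 2L])]] <- TRUE
  nbrs <- vector("list", n)
  for (r in seq_len(nrow(el))) {
    a <- el[r, 1L]; b <- el[r, 2L]
    nbrs[[a]] <- c(nbrs[[a]], b); nbrs[[b]] <- c(nbrs[[b]], a)
  }
  moved <- 0L; tries <- 0L
  while (moved < n_moves && tries < 20L * n_moves) {
    tries <- tries + 1L
    u <- sample.int(n, 1L)
    if (length(nbrs[[u]]) < 2L) next
    vw <- sample(nbrs[[u]], 2L)
    v <- min(vw); w <- max(vw)
    key <- paste(v, w)
    if (!is.null(seen[[key]])) next
    # remove a random edge not incident to the new triangle's corners
    cand <- which(!(el[, 1L] %in% c(u, v, w)) & !(el[, 2L] %in% c(u, v, w)))
    if (length(cand) == 0L) next
    drop <- cand[sample.int(length(cand), 1L)]
    a <- el[drop, 1L]; b <- el[drop, 2L]
    rm(list = paste(a, b), envir = seen)
    nbrs[[a]] <- setdiff(nbrs[[a]], b); nbrs[[b]] <- setdiff(nbrs[[b]], a)
    el[drop, ] <- c(v, w)
    seen[[key]] <- TRUE
    nbrs[[v]] <- c(nbrs[[v]], w); nbrs[[w]] <- c(nbrs[[w]], v)
    moved <- moved + 1L
  }
  el
}

draw_signs <- function(lo, hi, n, neg_fraction, skew) {
  m <- length(lo)
  if (skew == 0) {
    return(ifelse(stats::runif(m) < neg_fraction, -1L, 1L))
  }
  # two-point mixture with mean neg_fraction: a node is an
  # "inhibitor-like" high-propensity node with probability neg_fraction
  q_lo <- neg_fraction * (1 - skew)
  q_hi <- neg_fraction + skew * (1 - neg_fraction)
  q <- ifelse(stats::runif(n) < neg_fraction, q_hi, q_lo)
  p_edge <- (q[lo] + q[hi]) / 2
  ifelse(stats::runif(m) < p_edge, -1L, 1L)
}

#' Random stoichiometric reaction system
#'
#' Draws reactions with 1..`max_order` distinct reactants and 1..2
#' products, no species appearing on both sides, unit-or-double
#' coefficients. Deterministic given the seed; drives the
#' Jacobian-signature construction in tests and simulations.
#'
#' @param n_species number of species.
#' @param n_reactions number of reactions.
#' @param max_order maximum number of reactants per reaction (>= 1).
#' @param p_reversible probability that a reaction is reversible.
#' @param seed integer seed; `NULL` continues the current stream.
#' @return a [reaction_system()].
#' @export
random_reaction_system <- function(n_species, n_reactions, max_order = 2L,
                                   p_reversible = 0, seed = 0L) {
  stopifnot(max_order >= 1L, n_species >= max_order + 1L)
  if (!is.null(seed)) set.seed(seed)
  sp <- paste0("S", seq_len(n_species))
  rx <- lapply(seq_len(n_reactions), function(r) {
    k <- sample.int(max_order, 1L)
    re <- sample(sp, k)
    pr <- sample(setdiff(sp, re), sample.int(2L, 1L))
    list(reactants = stats::setNames(sample(1:2, length(re), TRUE), re),
         products = stats::setNames(sample(1:2, length(pr), TRUE), pr),
         reversible = stats::runif(1) < p_reversible)
  })
  reaction_system(sp, rx)
}

#' The 11-node yeast cell-cycle signed network
#'
#' The directed signed interaction graph of the budding-yeast cell-cycle
#' boolean model of Li et al. (PNAS 101:4781, 2004), shipped as a packaged
#' plain-text fixture (see
#' `system.file("extdata", "yeast_cell_cycle.tsv", package = "frustral")`).
#' It has 11 nodes, 15 activating and 14 inhibiting non-self edges, plus 5
#' inhibitory self-degradation loops. Symmetrizing (self-loops dropped)
#' leaves 23 undirected edges of which 10 are negative, with exactly one
#' incompatible directed pair removed; the exact frustration index of the
#' symmetrized network is 4.
#'
#' @return a [directed_signed_network()].
#' @export
yeast_cell_cycle_network <- function() {
  path <- system.file("extdata", "yeast_cell_cycle.tsv",
                      package = "frustral", mustWork = TRUE)
  read_signed_edge_list(path, directed = TRUE)
}
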