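#' Construct an undirected signed network
#'
#' The central container of the package: a simple undirected graph whose
#' edges carry a sign in \{+1, -1\} (activation / inhibition). It plays the
#' role of the symmetric signed adjacency matrix J with zero diagonal of the
#' Ising energy \eqn{h(s) = -\sum_{(i,j)} J_{ij} s_i s_j}.
#'
#' @param nodes character vector of node labels (order is preserved and
#'   defines the index of every spin/gauge vector).
#' @param edges data frame with columns `from`, `to` (node labels or integer
#'   indices) and `sign` (+1 or -1). Each unordered pair may appear once;
#'   self-loops are not allowed.
#' @return An object of class `signed_network` with elements `nodes`
#'   (character) and `edges` (data frame `from`, `to`, `sign` with integer
#'   node indices, `from < to`).
#' @examples
#' tri <- signed_network(c("a", "b", "c"),
#'                       data.frame(from = c("a", "b", "a"),
#'                                  to   = c("b", "c", "c"),
#'                                  sign = c(1, 1, -1)))
#' n_edges(tri)
#' @export
signed_network <- function(nodes, edges = NULL) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicate node labels")
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(from = integer(0), to = integer(0), sign = integer(0))
  } else {
    from <- resolve_nodes(edges$from, nodes)
    to <- resolve_nodes(edges$to, nodes)
    sign <- as.integer(edges$sign)
    if (!all(sign %in% c(-1L, 1L))) stop("edge signs must be +1 or -1")
    if (any(from == to)) stop("self-loops are not allowed in a signed_network")
    lo <- pmin(from, to); hi <- pmax(from, to)
    key <- paste(lo, hi)
    if (anyDuplicated(key)) stop("duplicate edges")
    edges <- data.frame(from = lo, to = hi, sign = sign)
  }
  structure(list(nodes = nodes, edges = edges), class = "signed_network")
}

#' Construct a directed signed network
#'
#' Directed counterpart of [signed_network()]: the sign pattern of a Jacobian
#' matrix, edge `source -> target` meaning the source variable activates
#' (+1) or inhibits (-1) the target. Self-loops are allowed (they are
#' conventionally dropped on symmetrization).
#'
#' @param nodes character vector of node labels.
#' @param edges data frame with columns `from`, `to`, `sign` as in
#'   [signed_network()]; ordered pairs must be unique.
#' @return An object of class `directed_signed_network`.
#' @export
directed_signed_network <- function(nodes, edges = NULL) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicate node labels")
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(from = integer(0), to = integer(0), sign = integer(0))
  } else {
    from <- resolve_nodes(edges$from, nodes)
    to <- resolve_nodes(edges$to, nodes)
    sign <- as.integer(edges$sign)
    if (!all(sign %in% c(-1L, 1L))) stop("edge signs must be +1 or -1")
    if (anyDuplicated(paste(from, to))) stop("duplicate directed edges")
    edges <- data.frame(from = from, to = to, sign = sign)
  }
  structure(list(nodes = nodes, edges = edges),
            class = "directed_signed_network")
}

resolve_nodes <- function(x, nodes) {
  if (is.numeric(x)) {
    idx <- as.integer(x)
    if (any(idx < 1L | idx > length(nodes))) stop("node index out of range")
    return(idx)
  }
  idx <- match(as.character(x), nodes)
  if (anyNA(idx)) stop("unknown node label: ", paste(unique(x[is.na(idx)]), collapse = ", "))
  idx
}

#' @export
print.signed_network <- function(x, ...) {
  m <- nrow(x$edges)
  cat(sprintf("signed_network: %d nodes, %d edges (%d negative)\n",
              length(x$nodes), m, sum(x$edges$sign < 0)))
  invisible(x)
}

#' @export
print.directed_signed_network <- function(x, ...) {
  m <- nrow(x$edges)
  cat(sprintf("directed_signed_network: %d nodes, %d edges (%d negative, %d self-loops)\n",
              length(x$nodes), m, sum(x$edges$sign < 0),
              sum(x$edges$from == x$edges$to)))
  invisible(x)
}

#' Number of nodes / edges of a signed network
#' @param net a `signed_network` or `directed_signed_network`.
#' @return integer count.
#' @export
n_nodes <- function(net) length(net$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(net) nrow(net$edges)

#' Number of negative edges
#' @param net a `signed_network` or `directed_signed_network`.
#' @return integer count of edges with sign -1.
#' @export
n_negative_edges <- function(net) sum(net$edges$sign < 0L)

#' Signed adjacency matrix
#'
#' @param net a `signed_network` or `directed_signed_network`.
#' @return integer matrix with entries in \{-1, 0, 1\}; symmetric with zero
#'   diagonal for undirected input.
#' @export
adjacency_matrix <- function(net) {
  n <- n_nodes(net)
  J <- matrix(0L, n, n, dimnames = list(net$nodes, net$nodes))
  e <- net$edges
  if (nrow(e)) {
    J[cbind(e$from, e$to)] <- e$sign
    if (inherits(net, "signed_network")) J[cbind(e$to, e$from)] <- e$sign
  }
  J
}

# neighbor list: for each node, data frame of (nbr, sign)
adjacency_list <- function(net) {
  n <- n_nodes(net)
  e <- net$edges
  nbr <- vector("list", n)
  sgn <- vector("list", n)
  if (nrow(e)) {
    ends <- c(e$from, e$to)
    other <- c(e$to, e$from)
    ss <- c(e$sign, e$sign)
    ord <- order(ends)
    ends <- ends[ord]; other <- other[ord]; ss <- ss[ord]
    runs <- split(seq_along(ends), ends)
    for (k in names(runs)) {
      i <- as.integer(k)
      nbr[[i]] <- other[runs[[k]]]
      sgn[[i]] <- ss[runs[[k]]]
    }
  }
  for (i in seq_len(n)) {
    if (is.null(nbr[[i]])) { nbr[[i]] <- integer(0); sgn[[i]] <- integer(0) }
  }
  list(nbr = nbr, sign = sgn)
}

as_igraph <- function(net) {
  g <- igraph::make_empty_graph(n = n_nodes(net),
                                directed = inherits(net, "directed_signed_network"))
  e <- net$edges
  if (nrow(e)) g <- igraph::add_edges(g, rbind(e$from, e$to))
  g
}

#' Connected components of a signed network
#'
#' @param net a `signed_network`.
#' @return list with `membership` (integer per node) and `count`.
#' @export
network_components <- function(net) {
  if (n_nodes(net) == 0L) return(list(membership = integer(0), count = 0L))
  comp <- igraph::components(as_igraph(net))
  list(membership = as.integer(comp$membership), count = comp$no)
}

# induced subnetwork on a set of node indices (keeps label identity)
induced_subnetwork <- function(net, keep) {
  keep <- sort(unique(as.integer(keep)))
  map <- integer(n_nodes(net)); map[keep] <- seq_along(keep)
  e <- net$edges
  sel <- e$from %in% keep & e$to %in% keep
  signed_network(net$nodes[keep],
                 data.frame(from = map[e$from[sel]], to = map[e$to[sel]],
                            sign = e$sign[sel]))
}

check_spin <- function(net, s, what = "spin state") {
  if (length(s) != n_nodes(net))
    stop(what, " length (", length(s), ") does not match node count (",
         n_nodes(net), ")")
  s <- as.integer(s)
  if (!all(s %in% c(-1L, 1L))) stop(what, " entries must be +1 or -1")
  s
}
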