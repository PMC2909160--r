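#' Is a spin state a local energy minimum?
#'
#' `TRUE` iff no single spin flip strictly decreases h(s).
#'
#' @param net a [signed_network()].
#' @param s spin state.
#' @return logical flag.
#' @export
is_local_minimum <- function(net, s) {
  s <- check_spin(net, s)
  e <- net$edges
  if (nrow(e) == 0L) return(TRUE)
  n <- n_nodes(net)
  # local field f_i = sum_j J_ij s_j; flipping i changes h by 2 s_i f_i
  contrib <- e$sign * s[e$from] * s[e$to]
  f <- numeric(n)
  tf <- tapply(c(contrib, contrib), c(e$from, e$to), sum)
  f[as.integer(names(tf))] <- tf
  all(2 * f >= 0)
}

#' Census of energy-landscape minima from random starts
#'
#' Runs seeded greedy descent (random-order sweeps, flips accepted only on
#' strict energy decrease, repeated until a fixed point) from `n_starts`
#' uniformly random spin states, deduplicates the resulting minima as
#' exact states (the global flip symmetry is handled at histogram time),
#' and labels global the states attaining the census minimum energy.
#'
#' @param net a [signed_network()].
#' @param n_starts number of random initial conditions (>= 1).
#' @param seed integer seed; `NULL` continues the current stream.
#' @return object of class `minima_census`: list with `states` (matrix,
#'   one row per distinct minimum), `energy`, `multiplicity` (times each
#'   was reached), `label` ("global"/"local"), `global_energy`, `n`
#'   (node count), `n_starts`.
#' @export
collect_minima <- function(net, n_starts, seed = 0L) {
  stopifnot(inherits(net, "signed_network"), n_starts >= 1L)
  if (!is.null(seed)) set.seed(seed)
  csr <- as_csr(net)
  raw <- cpp_collect_minima(csr$ptr, csr$nbr, csr$sgn,
                            as.integer(n_starts), n_edges(net))
  key <- apply(raw$states, 1L, paste, collapse = "")
  first <- !duplicated(key)
  states <- raw$states[first, , drop = FALSE]
  energies <- raw$energies[first]
  multiplicity <- as.integer(table(key)[key[first]])
  gmin <- min(energies)
  structure(list(states = states, energy = energies,
                 multiplicity = multiplicity,
                 label = ifelse(energies == gmin, "global", "local"),
                 global_energy = gmin, n = n_nodes(net),
                 n_starts = n_starts),
            class = "minima_census")
}

#' @export
print.minima_census <- function(x, ...) {
  cat(sprintf("minima_census: %d distinct minima from %d starts (%d global, energy %g)\n",
              length(x$energy), x$n_starts, sum(x$label == "global"),
              x$global_energy))
  invisible(x)
}

#' Pairwise Hamming distances between landscape minima
#'
#' Relative Hamming distance (differing spins over node count) for every
#' unordered pair of distinct minima in the requested class. With
#' `fold_symmetry`, distance d is reported as min(d, 1 - d): the minima
#' come in global-spin-flip pairs, so the histogram has a symmetry axis at
#' 1/2.
#'
#' @param census a [collect_minima()] result.
#' @param pair_class one of `"global-global"`, `"global-local"`,
#'   `"local-local"`.
#' @param fold_symmetry fold distances across the global-flip axis.
#' @param breaks histogram breaks (passed to [hist()]).
#' @return list with `distances` (numeric vector, possibly empty) and
#'   `histogram` (a `histogram` object, or `NULL` when the class is
#'   empty).
#' @export
pairwise_minima_distances <- function(census,
                                      pair_class = c("global-global",
                                                     "global-local",
                                                     "local-local"),
                                      fold_symmetry = FALSE, breaks = 20L) {
  pair_class <- match.arg(pair_class)
  lab <- census$label
  k <- length(lab)
  a_idx <- switch(pair_class,
                  "global-global" = which(lab == "global"),
                  "global-local" = which(lab == "global"),
                  "local-local" = which(lab == "local"))
  b_idx <- switch(pair_class,
                  "global-global" = which(lab == "global"),
                  "global-local" = which(lab == "local"),
                  "local-local" = which(lab == "local"))
  d <- numeric(0)
  if (length(a_idx) && length(b_idx)) {
    if (pair_class == "global-local") {
      pairs <- expand.grid(a = a_idx, b = b_idx)
    } else if (length(a_idx) >= 2L) {
      cmb <- utils::combn(a_idx, 2L)
      pairs <- data.frame(a = cmb[1L, ], b = cmb[2L, ])
    } else pairs <- data.frame(a = integer(0), b = integer(0))
    if (nrow(pairs)) {
      d <- vapply(seq_len(nrow(pairs)), function(r) {
        sum(census$states[pairs$a[r], ] != census$states[pairs$b[r], ]) / census$n
      }, numeric(1))
    }
  }
  if (fold_symmetry) d <- pmin(d, 1 - d)
  hg <- if (length(d)) {
    graphics::hist(d, breaks = seq(0, if (fold_symmetry) 0.5 else 1,
                         length.out = breaks + 1L), plot = FALSE)
  } else NULL
  list(distances = d, histogram = hg, pair_class = pair_class,
       fold_symmetry = fold_symmetry)
}

#' Monte-Carlo trajectory connecting two spin states
#'
#' Flips exactly the spins on which the two states differ, one per step,
#' in seeded random order: the number of moves equals the Hamming distance
#' between the states. The energy is recorded at every step, exposing the
#' barrier crossed between two minima.
#'
#' @param net a [signed_network()].
#' @param s_from,s_to spin states.
#' @param seed integer seed; `NULL` continues the current stream.
#' @return object of class `trajectory_profile`: data frame with columns
#'   `step` (0..Hamming distance), `distance` (relative Hamming distance
#'   from `s_from`), `energy`.
#' @export
interminimum_trajectory <- function(net, s_from, s_to, seed = 0L) {
  s_from <- check_spin(net, s_from); s_to <- check_spin(net, s_to)
  if (!is.null(seed)) set.seed(seed)
  n <- n_nodes(net)
  diff_idx <- which(s_from != s_to)
  order <- if (length(diff_idx) > 1L) sample(diff_idx) else diff_idx
  adj <- adjacency_list(net)
  s <- s_from
  h <- energy(net, s)
  out <- data.frame(step = 0L, distance = 0, energy = h)
  for (t in seq_along(order)) {
    i <- order[t]
    f <- sum(adj$sign[[i]] * s[adj$nbr[[i]]])
    h <- h + 2 * s[i] * f
    s[i] <- -s[i]
    out <- rbind(out, data.frame(step = t, distance = t / n, energy = h))
  }
  class(out) <- c("trajectory_profile", "data.frame")
  out
}

#' Average energy gradient around a minimum
#'
#' Launches `n_traj` seeded random single-flip walks from `start` (a walk
#' never revisits a node it has already flipped, so step d is at Hamming
#' distance d from the start) and averages, per distance, the energy
#' increment h(step d) - h(step d-1). A peak of this mean gradient marks
#' the rim of the energy barrier around the well of `start`.
#'
#' @param net a [signed_network()].
#' @param start spin state to start from (typically a global minimum).
#' @param n_traj number of walks.
#' @param horizon walk length (clipped to the node count with a warning).
#' @param seed integer seed; `NULL` continues the current stream.
#' @return data frame with columns `distance` (relative Hamming
#'   distance), `mean_increment`, `se` (standard error over walks), and
#'   `mean_energy`.
#' @export
average_gradient_profile <- function(net, start, n_traj = 1000L, horizon,
                                     seed = 0L) {
  start <- check_spin(net, start)
  n <- n_nodes(net)
  if (horizon > n) {
    warning("horizon clipped from ", horizon, " to n = ", n)
    horizon <- n
  }
  stopifnot(horizon >= 1L, n_traj >= 1L)
  if (!is.null(seed)) set.seed(seed)
  adj <- adjacency_list(net)
  h0 <- energy(net, start)
  inc <- matrix(NA_real_, n_traj, horizon)
  hmat <- matrix(NA_real_, n_traj, horizon)
  for (w in seq_len(n_traj)) {
    path <- sample.int(n, horizon)
    s <- start
    h <- h0
    for (d in seq_len(horizon)) {
      i <- path[d]
      f <- sum(adj$sign[[i]] * s[adj$nbr[[i]]])
      dh <- 2 * s[i] * f
      h <- h + dh
      s[i] <- -s[i]
      inc[w, d] <- dh
      hmat[w, d] <- h
    }
  }
  data.frame(distance = seq_len(horizon) / n,
             mean_increment = colMeans(inc),
             se = apply(inc, 2L, stats::sd) / sqrt(n_traj),
             mean_energy = colMeans(hmat))
}
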