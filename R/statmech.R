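# energies of all 2^n spin states, chunked (state code bit i = spin i up)
enumerate_energies <- function(net, chunk = 65536L) {
  n <- n_nodes(net)
  e <- net$edges
  n_states <- 2^n
  h <- numeric(n_states)
  for (start in seq(0, n_states - 1, by = chunk)) {
    codes <- start:min(start + chunk - 1, n_states - 1)
    S <- matrix(1, nrow = n, ncol = length(codes))
    for (b in seq_len(n))
      S[b, ] <- 1 - 2 * (bitwAnd(codes, bitwShiftL(1L, b - 1L)) > 0)
    h[codes + 1] <- if (nrow(e))
      -colSums(e$sign * S[e$from, , drop = FALSE] * S[e$to, , drop = FALSE])
    else 0
  }
  h
}

log_sum_exp <- function(x) {
  mx <- max(x)
  mx + log(sum(exp(x - mx)))
}

#' Exact Boltzmann thermodynamics by state enumeration
#'
#' Computes, for each interaction strength beta, the partition function
#' \eqn{Z(\beta) = \sum_s e^{-\beta h(s)}} over all 2^n spin states, the
#' internal energy \eqn{\langle h \rangle = \sum_s h(s) p(s)} with
#' \eqn{p(s) = e^{-\beta h(s)}/Z}, and the total probability of the
#' (usually degenerate) ground states. All sums are carried out in the log
#' domain.
#'
#' @param net a [signed_network()] with at most `max_nodes` nodes.
#' @param beta numeric vector of interaction strengths (>= 0).
#' @param max_nodes enumeration guard (default 20).
#' @return object of class `thermo_result`: data frame with columns
#'   `beta`, `log_Z`, `internal_energy`, `ground_probability`; attributes
#'   `ground_energy` and `ground_degeneracy`.
#' @export
exact_thermo <- function(net, beta, max_nodes = 20L) {
  n <- n_nodes(net)
  if (n > max_nodes)
    stop("exact enumeration needs n <= ", max_nodes,
         " (got ", n, "); use mean_field_solve()")
  stopifnot(all(beta >= 0))
  h <- enumerate_energies(net)
  h_min <- min(h)
  degeneracy <- sum(h == h_min)
  res <- data.frame(beta = beta, log_Z = NA_real_,
                    internal_energy = NA_real_,
                    ground_probability = NA_real_)
  for (i in seq_along(beta)) {
    b <- beta[i]
    lw <- -b * h
    lz <- log_sum_exp(lw)
    p <- exp(lw - lz)
    res$log_Z[i] <- lz
    # at beta = 0 the measure is exactly uniform and every edge term
    # averages to zero; mean() keeps the integer cancellation exact
    res$internal_energy[i] <- if (b == 0) mean(h) else sum(h * p)
    res$ground_probability[i] <- degeneracy * exp(-b * h_min - lz)
  }
  structure(res, ground_energy = h_min, ground_degeneracy = degeneracy,
            class = c("thermo_result", "data.frame"))
}

# one heterogeneous mean-field fixed point at a single beta
mf_fixed_point <- function(prof, beta, m_init, tol, max_iter, damping) {
  if (length(prof$k) == 0L)
    return(list(m_k = numeric(0), theta = 0, converged = TRUE, residual = 0))
  m_k <- m_init
  kp <- prof$k * prof$p_k / prof$mean_k
  for (it in seq_len(max_iter)) {
    theta <- sum(kp * m_k)
    m_new <- tanh(beta * prof$k_pn * theta)
    resid <- max(abs(m_new - m_k))
    m_k <- (1 - damping) * m_new + damping * m_k
    if (resid < tol) {
      return(list(m_k = m_k, theta = sum(kp * m_k), converged = TRUE,
                  residual = resid))
    }
  }
  list(m_k = m_k, theta = sum(kp * m_k), converged = FALSE, residual = resid)
}

#' Frustration-corrected heterogeneous mean field
#'
#' Solves, on a grid of interaction strengths beta, the self-consistency
#' system of the heterogeneous (degree-class) mean field in the
#' gauge-transformed basis, with the frustration correction that replaces
#' the degree k of each class by k_pn, the class-mean difference between
#' positive and negative incident edges:
#' \deqn{\langle s_{\sigma,k} \rangle = \tanh(\beta\, k_{pn}(k)\, \theta),
#'   \quad \theta = \sum_\ell \frac{k(\ell) p_k(\ell)}{\langle k \rangle}
#'   \langle s_{\sigma,k(\ell)} \rangle,}
#' with the global order parameter
#' \eqn{\langle s_\sigma \rangle = \sum_\ell p_k(\ell) \langle s_{\sigma,k(\ell)} \rangle}
#' and mean-field energy
#' \eqn{h_{mf} = -\frac{n}{2} \sum_\ell p_k(\ell) k_{pn}(\ell)
#'   \langle s_{\sigma,k(\ell)} \rangle \theta.}
#' Each beta is warm-started from the previous solution (floored at `init`
#' so the iteration can leave the trivial zero fixed point above the
#' transition); the positive branch is selected by the positive
#' initialization.
#'
#' @param net a [signed_network()].
#' @param gauge the frustration-minimizing gauge (from
#'   [minimize_frustration()]); the profile is computed on the gauged
#'   network, where k_pn is close to k.
#' @param beta_grid increasing grid of beta values (default 100 log-spaced
#'   points in \[0.01, 5\]).
#' @param init initial per-class magnetization for symmetry breaking.
#' @param tol fixed-point residual tolerance.
#' @param max_iter iteration cap per beta.
#' @param damping damping factor of the fixed-point update.
#' @return object of class `mean_field_result`: list with `beta`,
#'   `s_sigma` (global order parameter), `h_mf`, `theta`, `m_k` (matrix
#'   beta x degree class), `profile`, and the solver settings.
#' @export
mean_field_solve <- function(net, gauge,
                             beta_grid = default_beta_grid(),
                             init = 0.1, tol = 1e-13, max_iter = 1e5,
                             damping = 0.5) {
  stopifnot(inherits(net, "signed_network"), tol > 0,
            !is.unsorted(beta_grid))
  gauged <- apply_gauge(net, gauge)
  prof <- degree_profile(gauged)
  nb <- length(beta_grid)
  nc <- length(prof$k)
  m_k <- matrix(NA_real_, nb, nc)
  s_sigma <- h_mf <- theta <- numeric(nb)
  m_prev <- rep(init, nc)
  for (i in seq_len(nb)) {
    fp <- mf_fixed_point(prof, beta_grid[i], pmax(m_prev, init),
                         tol, max_iter, damping)
    if (!fp$converged)
      stop(sprintf("mean field did not converge at beta = %g (residual %g)",
                   beta_grid[i], fp$residual))
    m_k[i, ] <- fp$m_k
    theta[i] <- fp$theta
    s_sigma[i] <- sum(prof$p_k * fp$m_k)
    h_mf[i] <- -(prof$n / 2) * sum(prof$p_k * prof$k_pn * fp$m_k) * fp$theta
    m_prev <- fp$m_k
  }
  structure(list(beta = beta_grid, s_sigma = s_sigma, h_mf = h_mf,
                 theta = theta, m_k = m_k, profile = prof, init = init,
                 tol = tol, max_iter = max_iter, damping = damping),
            class = "mean_field_result")
}

#' Default beta grid: 100 log-spaced interaction strengths in \[0.01, 5\]
#' @param n_points number of grid points.
#' @param beta_min,beta_max grid range.
#' @return numeric vector.
#' @export
default_beta_grid <- function(n_points = 100L, beta_min = 0.01,
                              beta_max = 5) {
  exp(seq(log(beta_min), log(beta_max), length.out = n_points))
}

#' @export
print.mean_field_result <- function(x, ...) {
  cat(sprintf("mean_field_result: %d beta points in [%g, %g]; <s_sigma> up to %.4f\n",
              length(x$beta), min(x$beta), max(x$beta), max(x$s_sigma)))
  invisible(x)
}

#' Interaction strength needed for an ordered response
#'
#' Smallest beta at which the mean-field order parameter reaches `level`
#' (the 0.8 threshold is the conventional "ordered response" cutoff).
#' The grid crossing is refined by bisection, re-solving the
#' self-consistency system at each probe, to a beta tolerance of 1e-4.
#'
#' @param mf a [mean_field_solve()] result.
#' @param level order-parameter threshold in (0, 1).
#' @param beta_tol bisection tolerance on beta.
#' @return the threshold beta (numeric scalar).
#' @export
order_threshold <- function(mf, level = 0.8, beta_tol = 1e-4) {
  stopifnot(inherits(mf, "mean_field_result"), level > 0, level < 1)
  idx <- which(mf$s_sigma >= level)
  if (length(idx) == 0L)
    stop(sprintf("order parameter never reaches %g on the grid (max %.4f)",
                 level, max(mf$s_sigma)))
  i <- idx[1L]
  if (i == 1L) return(mf$beta[1L])
  lo <- mf$beta[i - 1L]; hi <- mf$beta[i]
  m_lo <- pmax(mf$m_k[i - 1L, ], mf$init)
  prof <- mf$profile
  while (hi - lo > beta_tol) {
    mid <- (lo + hi) / 2
    fp <- mf_fixed_point(prof, mid, m_lo, mf$tol, mf$max_iter, mf$damping)
    if (sum(prof$p_k * fp$m_k) >= level) hi <- mid
    else { lo <- mid; m_lo <- pmax(fp$m_k, mf$init) }
  }
  hi
}

#' Metropolis sampling of the Boltzmann distribution
#'
#' Single-spin-flip Metropolis chain at inverse-energy parameter beta with
#' acceptance min(1, exp(-beta * dh)); one sweep proposes n flips at
#' uniformly random nodes. Estimates of the internal energy and of the
#' magnetization in the gauge basis come with standard errors from batch
#' means. Deterministic for a fixed seed.
#'
#' @param net a [signed_network()].
#' @param beta interaction strength (>= 0).
#' @param sweeps total sweeps (> `burn_in`).
#' @param burn_in sweeps discarded before recording.
#' @param seed integer seed; `NULL` continues the current stream.
#' @param gauge basis for the magnetization (default all +1 = raw spins);
#'   pass the optimal gauge for the order parameter.
#' @param s_init initial spin state (default uniformly random).
#' @param record_states keep per-sweep state codes (for small n) so that
#'   sampled state frequencies can be compared to [exact_thermo()].
#' @param n_batches batch count for batch-means standard errors.
#' @return object of class `metropolis_result`: `h_mean`, `h_se`,
#'   `mag_mean`, `mag_se`, `acceptance`, `samples` (data frame with
#'   per-sweep `h` and `magnetization`, plus `state_code` if recorded).
#' @export
metropolis_sample <- function(net, beta, sweeps, burn_in = 0L, seed = 0L,
                              gauge = NULL, s_init = NULL,
                              record_states = FALSE, n_batches = 20L) {
  stopifnot(inherits(net, "signed_network"), beta >= 0, sweeps > burn_in,
            burn_in >= 0)
  n <- n_nodes(net)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(gauge)) gauge <- rep(1L, n) else gauge <- check_spin(net, gauge, "gauge")
  if (is.null(s_init)) s_init <- sample(c(-1L, 1L), n, replace = TRUE)
  else s_init <- check_spin(net, s_init)
  if (record_states && n > 30L)
    stop("state recording supported for n <= 30")
  csr <- as_csr(net)
  raw <- cpp_metropolis(csr$ptr, csr$nbr, csr$sgn, beta,
                        as.integer(sweeps), as.integer(burn_in),
                        s_init, gauge, record_states)
  batch_se <- function(x) {
    nb <- min(n_batches, length(x))
    means <- vapply(split(x, cut(seq_along(x), nb, labels = FALSE)),
                    mean, numeric(1))
    stats::sd(means) / sqrt(nb)
  }
  samples <- data.frame(h = raw$h, magnetization = raw$magnetization)
  if (record_states) samples$state_code <- raw$state_code
  structure(list(h_mean = mean(raw$h), h_se = batch_se(raw$h),
                 mag_mean = mean(raw$magnetization),
                 mag_se = batch_se(raw$magnetization),
                 acceptance = raw$acceptance, samples = samples,
                 final_state = raw$final_state,
                 beta = beta, sweeps = sweeps, burn_in = burn_in),
            class = "metropolis_result")
}

#' @export
print.metropolis_result <- function(x, ...) {
  cat(sprintf("metropolis_result: beta = %g, %d sweeps (%d burn-in); <h> = %.4f +/- %.4f, m = %.4f +/- %.4f, acceptance %.3f\n",
              x$beta, x$sweeps, x$burn_in, x$h_mean, x$h_se, x$mag_mean,
              x$mag_se, x$acceptance))
  invisible(x)
}
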