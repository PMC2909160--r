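#' Configuration for a full frustration analysis run
#'
#' @param input a [signed_network()], a [directed_signed_network()] (it is
#'   symmetrized first), a [generator_config()], or a path to a signed
#'   edge-list file.
#' @param seed master seed; every stage draws from the stream it starts.
#' @param restarts annealing restarts for the frustration heuristic.
#' @param null_replicates sign-reshuffling replicates for the null model
#'   and the sign-packing Z (0 disables both stages).
#' @param beta_grid interaction-strength grid for the thermodynamics.
#' @param landscape_starts random starts for the minima census.
#' @param n_traj trajectories for the average gradient profile.
#' @param horizon gradient-walk length (default half the node count).
#' @param out_dir output directory, or `NULL` to skip writing files.
#' @return a `run_config` list.
#' @export
run_config <- function(input, seed = 0L, restarts = 50L,
                       null_replicates = 1000L,
                       beta_grid = default_beta_grid(),
                       landscape_starts = 500L, n_traj = 1000L,
                       horizon = NULL, out_dir = NULL) {
  stopifnot(restarts >= 1L, null_replicates >= 0L, landscape_starts >= 1L,
            n_traj >= 1L, all(beta_grid >= 0))
  structure(list(input = input, seed = as.integer(seed),
                 restarts = as.integer(restarts),
                 null_replicates = as.integer(null_replicates),
                 beta_grid = beta_grid,
                 landscape_starts = as.integer(landscape_starts),
                 n_traj = as.integer(n_traj), horizon = horizon,
                 out_dir = out_dir),
            class = "run_config")
}

resolve_input <- function(input) {
  if (inherits(input, "signed_network"))
    return(list(network = input, conflicts = 0L))
  if (inherits(input, "directed_signed_network"))
    return(symmetrize(input))
  if (inherits(input, "generator_config"))
    return(list(network = random_signed_graph(input), conflicts = 0L))
  if (is.character(input) && length(input) == 1L) {
    d <- read_signed_edge_list(input, directed = TRUE)
    return(symmetrize(d))
  }
  stop("unsupported input type")
}

config_fingerprint <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  desc <- cfg
  desc$input <- if (is.character(cfg$input)) cfg$input else class(cfg$input)[1L]
  desc$out_dir <- NULL
  jsonlite::write_json(desc, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

stage <- function(name, expr) {
  t0 <- proc.time()[["elapsed"]]
  out <- tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s': %s", name, conditionMessage(e)), call. = FALSE))
  message(sprintf("[%s] done in %.2fs", name, proc.time()[["elapsed"]] - t0))
  out
}

write_stamped_tsv <- function(df, path, hash, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# config_hash=%s seed=%d", hash, seed), con)
  utils::write.table(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full frustration / thermodynamics / landscape analysis
#'
#' Executes the package's analysis surface end to end on one network:
#' symmetrization (if directed), heuristic frustration minimization,
#' sign-reshuffling null model and sign-packing statistics, exact
#' thermodynamics (n <= 20) or the frustration-corrected mean field with
#' the 0.8 order threshold, and the energy-landscape census with distance
#' histograms and the average gradient profile. Fully reproducible from
#' (input, seed); when `out_dir` is set, writes a JSON frustration record,
#' thermo and landscape TSVs (each stamped with the config hash and seed)
#' and a human-readable summary.
#'
#' @param cfg a [run_config()].
#' @return the report, an invisible list with elements `network`,
#'   `conflicts`, `frustration`, `null`, `packing`, `thermo` (exact) or
#'   `mean_field`, `order_beta`, `census`, `distances`, `gradient`,
#'   `config_hash`.
#' @export
run_full_analysis <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  set.seed(cfg$seed)
  hash <- config_fingerprint(cfg)
  inp <- stage("input", resolve_input(cfg$input))
  net <- inp$network
  n <- n_nodes(net); m <- n_edges(net)

  fr <- stage("frustration",
              minimize_frustration(net, restarts = cfg$restarts, seed = NULL))

  degenerate_null <- n_negative_edges(net) %in% c(0L, m) ||
    cfg$null_replicates < 2L
  nm <- pk <- NULL
  if (!degenerate_null) {
    nm <- stage("null_model",
                null_model(net, replicates = cfg$null_replicates,
                           seed = NULL, restarts = max(cfg$restarts %/% 5L, 1L),
                           delta_up = fr$delta_up))
    pk <- stage("sign_packing",
                sign_packing(net, replicates = cfg$null_replicates,
                             seed = NULL))
  }

  thermo <- mf <- NULL
  order_beta <- NA_real_
  if (n <= 20L) {
    thermo <- stage("exact_thermo", exact_thermo(net, cfg$beta_grid))
  } else {
    mf <- stage("mean_field",
                mean_field_solve(net, fr$gauge, beta_grid = cfg$beta_grid))
    order_beta <- tryCatch(order_threshold(mf, 0.8),
                           error = function(e) NA_real_)
  }

  census <- stage("landscape",
                  collect_minima(net, n_starts = cfg$landscape_starts,
                                 seed = NULL))
  dists <- lapply(c("global-global", "global-local", "local-local"),
                  function(pc) pairwise_minima_distances(census, pc))
  names(dists) <- c("global-global", "global-local", "local-local")
  gstate <- census$states[which(census$label == "global")[1L], ]
  horizon <- if (is.null(cfg$horizon)) max(1L, n %/% 2L) else cfg$horizon
  grad <- stage("gradient",
                average_gradient_profile(net, gstate, n_traj = cfg$n_traj,
                                         horizon = horizon, seed = NULL))

  record <- list(
    config_hash = hash, seed = cfg$seed, n = n, m = m,
    negative_edges = n_negative_edges(net),
    symmetrization_conflicts = inp$conflicts,
    delta_low = fr$delta_low, delta_up = fr$delta_up,
    delta_max = delta_max_bound(net),
    ground_energy = fr$ground_energy,
    monotone = fr$balanced,
    delta_null = if (is.null(nm)) NA else nm$delta_null_mean,
    sigma_null = if (is.null(nm)) NA else nm$delta_null_sd,
    z_score = if (is.null(nm)) NA else nm$z_score,
    p_value = if (is.null(nm)) NA else nm$p_value,
    packing_z = if (is.null(pk)) NA else pk$z_score,
    order_beta = order_beta)

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(record, file.path(cfg$out_dir, "frustration.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    tdf <- if (!is.null(thermo)) {
      data.frame(beta = thermo$beta, internal_energy = thermo$internal_energy,
                 ground_probability = thermo$ground_probability)
    } else {
      data.frame(beta = mf$beta, order_parameter = mf$s_sigma,
                 h_mf = mf$h_mf)
    }
    write_stamped_tsv(tdf, file.path(cfg$out_dir, "thermo.tsv"), hash, cfg$seed)
    write_stamped_tsv(data.frame(energy = census$energy,
                                 multiplicity = census$multiplicity,
                                 label = census$label),
                      file.path(cfg$out_dir, "minima.tsv"), hash, cfg$seed)
    ddf <- do.call(rbind, lapply(names(dists), function(pc) {
      d <- dists[[pc]]$distances
      if (length(d)) data.frame(pair_class = pc, distance = d) else NULL
    }))
    if (!is.null(ddf))
      write_stamped_tsv(ddf, file.path(cfg$out_dir, "minima_distances.tsv"),
                        hash, cfg$seed)
    write_stamped_tsv(grad, file.path(cfg$out_dir, "gradient.tsv"),
                      hash, cfg$seed)
    summary_lines <- c(
      sprintf("frustral analysis (config %s, seed %d)", hash, cfg$seed),
      sprintf("network: %d nodes, %d edges (%d negative), %d symmetrization conflicts",
              n, m, record$negative_edges, inp$conflicts),
      sprintf("frustration index: delta in [%d, %d], delta_max = %d, ground energy %g%s",
              record$delta_low, record$delta_up, record$delta_max,
              record$ground_energy,
              if (record$monotone) " (monotone)" else ""),
      if (!is.null(nm)) sprintf("null model: %.2f +/- %.2f, Z = %.2f, p = %.3g",
                                nm$delta_null_mean, nm$delta_null_sd,
                                nm$z_score, nm$p_value)
      else "null model: degenerate (single-sign network) or disabled",
      if (!is.na(order_beta)) sprintf("order threshold (<s_sigma> >= 0.8): beta = %.4f",
                                      order_beta)
      else if (!is.null(thermo)) sprintf("exact thermodynamics on %d beta points (ground degeneracy %d)",
                                         nrow(thermo), attr(thermo, "ground_degeneracy"))
      else "order threshold not reached on the beta grid",
      sprintf("landscape: %d distinct minima (%d global) from %d starts",
              length(census$energy), sum(census$label == "global"),
              cfg$landscape_starts))
    writeLines(summary_lines, file.path(cfg$out_dir, "summary.txt"))
  }

  invisible(list(network = net, conflicts = inp$conflicts, frustration = fr,
                 null = nm, packing = pk, thermo = thermo, mean_field = mf,
                 order_beta = order_beta, census = census, distances = dists,
                 gradient = grad, record = record, config_hash = hash))
}
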