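#' Construct a stoichiometric reaction system
#'
#' @param species character vector of species names.
#' @param reactions list of reactions; each a list with `reactants` and
#'   `products` (named integer vectors of stoichiometric coefficients >= 1,
#'   names in `species`) and optional `reversible` flag (default `FALSE`).
#' @return object of class `reaction_system`.
#' @export
reaction_system <- function(species, reactions) {
  species <- as.character(species)
  if (anyDuplicated(species)) stop("duplicate species")
  reactions <- lapply(reactions, function(r) {
    if (is.null(r$reversible)) r$reversible <- FALSE
    if (length(r$reactants) == 0L) stop("a reaction must have at least one reactant")
    coef <- c(r$reactants, r$products)
    if (any(coef < 1L)) stop("stoichiometric coefficients must be >= 1")
    unknown <- setdiff(c(names(r$reactants), names(r$products)), species)
    if (length(unknown)) stop("unknown species: ", paste(unknown, collapse = ", "))
    r
  })
  structure(list(species = species, reactions = reactions),
            class = "reaction_system")
}

#' @export
print.reaction_system <- function(x, ...) {
  cat(sprintf("reaction_system: %d species, %d reactions (%d reversible)\n",
              length(x$species), length(x$reactions),
              sum(vapply(x$reactions, function(r) r$reversible, logical(1)))))
  invisible(x)
}

#' Signed interaction graph from the Jacobian sign pattern of a reaction system
#'
#' Assumes mass-action-like kinetics in which each reaction rate increases
#' in every reactant concentration. The partial derivative of the net
#' production of species i with respect to reactant j then has the sign of
#' the net stoichiometric change of i in that reaction: products are
#' activated and co-reactants inhibit each other (each raises the rate of
#' the reaction consuming the other). A reversible reaction contributes the
#' reverse direction as an independent reaction. Pairs (j, i) receiving
#' opposite-sign contributions from different reactions violate the
#' constant-sign assumption: they are excluded from the graph and counted
#' in a message.
#'
#' @param rs a [reaction_system()].
#' @return a [directed_signed_network()] on the species (self-effects
#'   omitted), with attribute `ambiguous` holding the number of excluded
#'   ambiguous ordered pairs.
#' @export
jacobian_signature_from_reactions <- function(rs) {
  stopifnot(inherits(rs, "reaction_system"))
  sp <- rs$species
  elem <- list()
  for (r in rs$reactions) {
    elem <- c(elem, list(r))
    if (r$reversible)
      elem <- c(elem, list(list(reactants = r$products, products = r$reactants)))
  }
  acc <- new.env(parent = emptyenv())  # "j|i" -> set of signs seen
  for (r in elem) {
    net_st <- stats::setNames(numeric(length(sp)), sp)
    net_st[names(r$reactants)] <- net_st[names(r$reactants)] - r$reactants
    net_st[names(r$products)] <- net_st[names(r$products)] + r$products
    affected <- names(net_st)[net_st != 0]
    for (j in names(r$reactants)) {
      for (i in affected) {
        if (i == j) next
        key <- paste(j, i, sep = "\r")
        acc[[key]] <- union(acc[[key]], sign(net_st[[i]]))
      }
    }
  }
  keys <- ls(acc)
  from <- character(0); to <- character(0); sgn <- integer(0)
  ambiguous <- 0L
  for (key in keys) {
    s <- acc[[key]]
    if (length(s) > 1L) { ambiguous <- ambiguous + 1L; next }
    ji <- strsplit(key, "\r", fixed = TRUE)[[1L]]
    from <- c(from, ji[1L]); to <- c(to, ji[2L]); sgn <- c(sgn, as.integer(s))
  }
  if (ambiguous > 0L)
    message(ambiguous, " ambiguous Jacobian entries (opposite signs from different reactions) excluded")
  out <- directed_signed_network(
    sp, data.frame(from = match(from, sp), to = match(to, sp), sign = sgn))
  attr(out, "ambiguous") <- ambiguous
  out
}
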