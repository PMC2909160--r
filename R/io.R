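SIGN_TOKENS <- c("+1" = 1L, "-1" = -1L, "+" = 1L, "-" = -1L, "1" = 1L,
                 "activation" = 1L, "inhibition" = -1L,
                 "activates" = 1L, "inhibits" = -1L)

parse_sign_token <- function(tok) {
  s <- SIGN_TOKENS[trimws(tolower(tok))]
  unname(s)
}

#' Read a signed edge list
#'
#' Parses tab- or comma-separated interaction files with columns
#' `source, target, sign` or the SIF-like variant
#' `source, relation, target` with relation in \{activates, inhibits\}.
#' Accepted sign tokens: `+1/-1`, `+/-`, `1/-1`, `activation/inhibition`.
#' An optional header line is skipped automatically.
#'
#' @param path path to the edge-list file.
#' @param directed logical; return a [directed_signed_network()] (keeping
#'   edge direction and any self-loops) or collapse to an undirected
#'   [signed_network()].
#' @return a `directed_signed_network` or `signed_network`. Node order is
#'   first-appearance order. Duplicate edges with equal sign are
#'   deduplicated; a duplicate with conflicting sign is an error naming the
#'   offending line.
#' @export
read_signed_edge_list <- function(path, directed = TRUE) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0L) {
    return(if (directed) directed_signed_network(character(0))
           else signed_network(character(0)))
  }
  fields <- lapply(lines, function(l) {
    f <- strsplit(l, "[\t,]")[[1]]
    trimws(f[nzchar(trimws(f))])
  })
  start <- 1L
  f1 <- fields[[1L]]
  if (length(f1) >= 3L &&
      all(tolower(f1[1:2]) %in% c("source", "target", "sign", "relation", "from", "to"))) {
    start <- 2L  # header line
  }
  src <- character(0); dst <- character(0); sgn <- integer(0)
  for (li in seq(start, length(fields))) {
    f <- fields[[li]]
    if (length(f) < 3L)
      stop(sprintf("line %d: expected 3 columns, found %d", li, length(f)))
    rel <- parse_sign_token(f[2L])
    if (!is.na(rel) && tolower(f[2L]) %in% c("activates", "inhibits",
                                             "activation", "inhibition")) {
      a <- f[1L]; b <- f[3L]; s <- rel    # SIF-like: source relation target
    } else {
      s <- parse_sign_token(f[3L])
      if (is.na(s))
        stop(sprintf("line %d: unparsable sign token '%s'", li, f[3L]))
      a <- f[1L]; b <- f[2L]
    }
    src <- c(src, a); dst <- c(dst, b); sgn <- c(sgn, s)
  }
  nodes <- unique(c(rbind(src, dst)))
  i <- match(src, nodes); j <- match(dst, nodes)
  if (!directed) {
    lo <- pmin(i, j); hi <- pmax(i, j); i <- lo; j <- hi
  }
  key <- paste(i, j)
  first <- !duplicated(key)
  dup <- which(!first)
  for (d in dup) {
    k <- match(key[d], key)
    if (sgn[k] != sgn[d])
      stop(sprintf("line %d: edge %s-%s already seen with opposite sign",
                   d + start - 1L, src[d], dst[d]))
  }
  edges <- data.frame(from = i[first], to = j[first], sign = sgn[first])
  if (directed) directed_signed_network(nodes, edges)
  else signed_network(nodes, edges)
}

#' Write a signed edge list
#'
#' Writes `source TAB target TAB sign` (+1/-1 tokens) with a header.
#'
#' @param net a `signed_network` or `directed_signed_network`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_signed_edge_list <- function(net, path) {
  e <- net$edges
  df <- data.frame(source = net$nodes[e$from], target = net$nodes[e$to],
                   sign = ifelse(e$sign > 0, "+1", "-1"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a reaction table
#'
#' Long-format TSV with columns `reaction_id, side, species, coefficient`
#' where `side` is `reactant` or `product` and coefficients are positive
#' integers. An optional `reversible` column (0/1, constant per reaction)
#' marks reversible reactions.
#'
#' @param path path to the reaction table.
#' @return a [reaction_system()].
#' @export
read_reaction_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("reaction_id", "side", "species", "coefficient")
  if (!all(need %in% names(df)))
    stop("reaction table needs columns: ", paste(need, collapse = ", "))
  species <- unique(df$species)
  rx <- lapply(split(df, df$reaction_id), function(d) {
    re <- d[d$side == "reactant", ]
    pr <- d[d$side == "product", ]
    list(reactants = stats::setNames(as.integer(re$coefficient), re$species),
         products = stats::setNames(as.integer(pr$coefficient), pr$species),
         reversible = if ("reversible" %in% names(d)) as.logical(d$reversible[1L]) else FALSE)
  })
  reaction_system(species, unname(rx))
}
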