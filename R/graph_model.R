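# Core graph model: extended-network construction from a seed list, connected
# component handling, induced subgraphs. Networks are simple undirected
# igraph objects with a vertex attribute `name` (the protein symbol) and a
# logical vertex attribute `seed`.

#' Build the extended network around a seed-gene set
#'
#' The extended network contains the seed proteins plus all of their direct
#' interaction partners at confidence `min_score` or above, together with
#' *all* interactions among that node set (induced edges between neighbours
#' are kept, not only seed-incident edges). Seeds absent from the interaction
#' table are kept as isolated flagged nodes when `keep_missing_seeds = TRUE`,
#' otherwise dropped with a warning.
#'
#' @param seeds character vector of seed symbols, or a seed `data.frame` from
#'   [read_seed_list()].
#' @param interactions cleaned interaction `data.frame` (`id_a`, `id_b`,
#'   `score` on the 0-1000 scale), e.g. from [read_interactions()].
#' @param min_score confidence threshold; rows below it are ignored.
#'   Default 400, the usual "medium confidence" convention for combined
#'   scores.
#' @param keep_missing_seeds keep seeds absent from the (filtered) table as
#'   isolated nodes instead of dropping them.
#' @param aliases optional two-column `data.frame` (`from`, `to`) remapping
#'   interaction-table identifiers to seed symbols before construction.
#' @return an `igraph` network with vertex attributes `name` and `seed`.
#' @examples
#' tab <- data.frame(id_a = c("A", "B", "A"), id_b = c("B", "C", "C"),
#'                   score = c(900, 900, 900))
#' net <- build_extended_network("A", tab)
#' igraph::vcount(net)  # 3: A plus neighbours B, C (B-C induced edge kept)
#' @export
build_extended_network <- function(seeds, interactions, min_score = 400,
                                   keep_missing_seeds = FALSE, aliases = NULL) {
  if (is.data.frame(seeds)) seeds <- seeds$symbol
  seeds <- normalize_symbol(seeds)
  if (length(seeds) == 0L) stop("no seed symbols supplied", call. = FALSE)
  seeds <- unique(seeds)
  tab <- clean_interactions(interactions)
  if (!is.null(aliases)) {
    map <- stats::setNames(normalize_symbol(aliases[[2]]),
                           normalize_symbol(aliases[[1]]))
    remap <- function(x) ifelse(x %in% names(map), unname(map[x]), x)
    tab$id_a <- remap(tab$id_a)
    tab$id_b <- remap(tab$id_b)
    tab <- clean_interactions(tab)
  }
  tab <- tab[tab$score >= min_score, , drop = FALSE]

  seed_hit <- tab$id_a %in% seeds | tab$id_b %in% seeds
  neighbours <- unique(c(tab$id_a[seed_hit], tab$id_b[seed_hit]))
  present_seeds <- seeds[seeds %in% c(tab$id_a, tab$id_b)]
  nodes <- sort(unique(c(present_seeds, neighbours)))

  missing <- setdiff(seeds, nodes)
  if (length(missing) > 0L) {
    if (keep_missing_seeds) {
      nodes <- sort(c(nodes, missing))
    } else {
      warning(warningCondition(
        paste0("seed(s) absent from the interaction table at min_score=",
               min_score, " dropped: ", paste(missing, collapse = ", ")),
        class = "seednet_missing_seeds"))
    }
  }
  if (length(nodes) == 0L) {
    stop("extended network is empty: no seed appears in the interaction table",
         call. = FALSE)
  }
  keep_edges <- tab$id_a %in% nodes & tab$id_b %in% nodes
  el <- tab[keep_edges, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    el, directed = FALSE,
    vertices = data.frame(name = nodes, seed = nodes %in% seeds,
                          stringsAsFactors = FALSE))
  g
}

#' Decompose a network into connected components
#'
#' Components are ordered by size, largest first; equal-sized components are
#' ordered by their lexicographically smallest member, so the decomposition
#' (and the giant component in particular) is deterministic.
#'
#' @param net an `igraph` network.
#' @return a `component_decomposition`: list with `components` (list of
#'   sorted node-name vectors), `sizes`, `giant` (node names of the largest
#'   component) and `giant_graph` (its induced subgraph).
#' @export
decompose_components <- function(net) {
  if (igraph::vcount(net) == 0L) stop("cannot decompose an empty network", call. = FALSE)
  comp <- igraph::components(net)
  groups <- split(igraph::V(net)$name, comp$membership)
  groups <- lapply(groups, sort)
  first_member <- vapply(groups, `[`, "", 1L)
  ord <- order(-lengths(groups), first_member)
  groups <- unname(groups[ord])
  structure(list(components = groups,
                 sizes = lengths(groups),
                 giant = groups[[1]],
                 giant_graph = induced_subnetwork(net, groups[[1]])),
            class = "component_decomposition")
}

#' @export
print.component_decomposition <- function(x, ...) {
  cat("Component decomposition:", length(x$components), "component(s); sizes:",
      paste(x$sizes, collapse = ", "), "\n")
  cat("Giant component:", length(x$giant), "nodes\n")
  invisible(x)
}

#' Induced subgraph on a node subset
#'
#' @param net an `igraph` network.
#' @param keep character vector of node names, a subset of the network's
#'   nodes.
#' @return the induced `igraph` subnetwork; seed flags are preserved.
#' @export
induced_subnetwork <- function(net, keep) {
  keep <- unique(keep)
  missing <- setdiff(keep, igraph::V(net)$name)
  if (length(missing) > 0L) {
    stop("node(s) not in the network: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  igraph::induced_subgraph(net, keep)
}

#' Seed flags of a network
#'
#' @param net an `igraph` network built by this package.
#' @return character vector of the node names flagged as seeds.
#' @export
seed_nodes <- function(net) {
  flags <- igraph::V(net)$seed
  if (is.null(flags)) return(character())
  igraph::V(net)$name[flags]
}
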