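# High-betweenness backbone extraction, hub/bottleneck key-node
# classification, and the subnetwork spanned by all shortest paths between
# seed genes.

#' Select the top fraction of nodes by score
#'
#' The cutoff count is `m = ceiling(fraction * n_total)` (so 5% of a 535-node
#' network keeps 27 nodes). Ties at the boundary are *included*, which can
#' grow the selection past `m`; whether that happened is recorded in the
#' `tie_inflated` attribute. Output order is deterministic: score descending,
#' then node name.
#'
#' @param values named numeric vector of scores (e.g. betweenness or degree).
#' @param n_total total node count the fraction refers to (defaults to
#'   `length(values)`).
#' @param fraction fraction in (0, 1]; default 0.05 (the "top 5%" rule).
#' @return `data.frame` with columns `rank`, `node`, `score`; attributes
#'   `m_nominal` (the ceiling count before tie inflation) and `tie_inflated`.
#' @export
select_top_fraction <- function(values, n_total = length(values), fraction = 0.05) {
  if (length(values) == 0L) stop("no scores supplied", call. = FALSE)
  if (fraction <= 0 || fraction > 1) stop("fraction must lie in (0, 1]", call. = FALSE)
  m <- min(as.integer(ceiling(fraction * n_total)), length(values))
  ord <- order(-values, names(values))
  sorted <- values[ord]
  threshold <- sorted[m]
  members <- sorted[sorted >= threshold]
  out <- data.frame(rank = seq_along(members),
                    node = names(members),
                    score = as.numeric(members),
                    stringsAsFactors = FALSE)
  attr(out, "m_nominal") <- m
  attr(out, "tie_inflated") <- nrow(out) > m
  out
}

#' Extract the high-betweenness backbone
#'
#' The backbone is the induced subgraph of the giant component on its
#' top-`fraction` nodes by betweenness centrality ("bottleneck" proteins).
#' It may be disconnected.
#'
#' @param giant the (connected) giant component.
#' @param bc optional precomputed betweenness (named vector); computed with
#'   [node_betweenness()] when `NULL`.
#' @param fraction cutoff fraction, default 0.05.
#' @return a `backbone_result`: list with `members` (ranked `data.frame` of
#'   node, score), `cutoff_count`, `m_nominal`, `fraction` and `graph`
#'   (the induced backbone network).
#' @export
extract_backbone <- function(giant, bc = NULL, fraction = 0.05) {
  if (is.null(bc)) bc <- node_betweenness(giant)
  members <- select_top_fraction(bc, igraph::vcount(giant), fraction)
  structure(list(members = members,
                 cutoff_count = nrow(members),
                 m_nominal = attr(members, "m_nominal"),
                 fraction = fraction,
                 graph = induced_subnetwork(giant, members$node)),
            class = "backbone_result")
}

#' @export
print.backbone_result <- function(x, ...) {
  cat(sprintf("Backbone: %d nodes (top %.0f%% by BC), %d edges; top node %s (BC %.5f)\n",
              x$cutoff_count, 100 * x$fraction, igraph::ecount(x$graph),
              x$members$node[1], x$members$score[1]))
  invisible(x)
}

#' Classify key nodes into hub/bottleneck categories
#'
#' Following the four-way scheme of Yu and colleagues: a *hub* is a node in
#' the top fraction by degree, a *bottleneck* one in the top fraction by
#' betweenness; every node gets one of the labels hub-bottleneck,
#' hub-nonbottleneck, nonhub-bottleneck or nonhub-nonbottleneck.
#'
#' @param degree named degree vector.
#' @param bc named betweenness vector over the same nodes.
#' @param n_total total node count (defaults to `length(degree)`).
#' @param fraction cutoff fraction for both rankings, default 0.05.
#' @return a `key_node_classification`: list with `table` (node, degree, bc,
#'   class), the three report sets `hub_bottleneck`, `bottleneck_only`,
#'   `hub_only`, and `counts` (a 4-way tally summing to `length(degree)`).
#' @export
classify_key_nodes <- function(degree, bc, n_total = length(degree), fraction = 0.05) {
  if (!setequal(names(degree), names(bc))) {
    stop("degree and betweenness must cover the same node set", call. = FALSE)
  }
  hubs <- select_top_fraction(degree, n_total, fraction)$node
  bottlenecks <- select_top_fraction(bc, n_total, fraction)$node
  nodes <- sort(names(degree))
  is_hub <- nodes %in% hubs
  is_bn <- nodes %in% bottlenecks
  cls <- ifelse(is_hub & is_bn, "hub-bottleneck",
         ifelse(is_hub, "hub-nonbottleneck",
         ifelse(is_bn, "nonhub-bottleneck", "nonhub-nonbottleneck")))
  tab <- data.frame(node = nodes,
                    degree = as.integer(degree[nodes]),
                    bc = as.numeric(bc[nodes]),
                    class = cls, stringsAsFactors = FALSE)
  tab <- tab[order(-tab$bc, -tab$degree, tab$node), , drop = FALSE]
  rownames(tab) <- NULL
  counts <- c("hub-bottleneck" = sum(is_hub & is_bn),
              "hub-nonbottleneck" = sum(is_hub & !is_bn),
              "nonhub-bottleneck" = sum(!is_hub & is_bn),
              "nonhub-nonbottleneck" = sum(!is_hub & !is_bn))
  structure(list(table = tab,
                 hub_bottleneck = sort(intersect(hubs, bottlenecks)),
                 bottleneck_only = sort(setdiff(bottlenecks, hubs)),
                 hub_only = sort(setdiff(hubs, bottlenecks)),
                 counts = counts),
            class = "key_node_classification")
}

#' @export
print.key_node_classification <- function(x, ...) {
  print(x$counts)
  invisible(x)
}

#' Subnetwork spanned by all shortest paths between seed genes
#'
#' For every unordered pair of seeds present in the giant component, *all*
#' distinct shortest paths are considered (not one representative): a node v
#' lies on a shortest s-t path exactly when d(s,v) + d(v,t) = d(s,t), which
#' is how membership is decided, so no path enumeration (and no combinatorial
#' explosion) is needed. The subnetwork is the *induced* subgraph on the
#' union of all such nodes; betweenness is recomputed within it.
#'
#' @param giant the connected giant component.
#' @param seeds character vector of seed symbols (silently restricted to
#'   those present in the giant component).
#' @return a `seed_subnetwork`: list with `nodes`, `graph` (induced),
#'   `bc_ranking` (centralities within the subnetwork), `seed_pairs`
#'   (per-pair shortest distances) and `seeds` (those used).
#' @export
seed_shortest_path_subnetwork <- function(giant, seeds) {
  assert_connected(giant, "seed shortest-path subnetwork")
  if (is.data.frame(seeds)) seeds <- seeds$symbol
  seeds <- sort(intersect(normalize_symbol(seeds), igraph::V(giant)$name))
  if (length(seeds) == 0L) stop("no seed is present in the giant component", call. = FALSE)
  all_names <- igraph::V(giant)$name
  d <- igraph::distances(giant, v = seeds, weights = NA)  # |seeds| x N
  colnames(d) <- all_names

  on_path <- rep(FALSE, length(all_names))
  names(on_path) <- all_names
  on_path[seeds] <- TRUE
  pairs <- utils::combn(seq_along(seeds), 2)
  pair_dist <- numeric(ncol(pairs))
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1, p]; j <- pairs[2, p]
    dst <- d[i, seeds[j]]
    pair_dist[p] <- dst
    on_path <- on_path | (d[i, ] + d[j, ] == dst)
  }
  nodes <- sort(all_names[on_path])
  sub <- induced_subnetwork(giant, nodes)
  structure(list(nodes = nodes,
                 graph = sub,
                 bc_ranking = node_centralities(sub),
                 seed_pairs = data.frame(seed_a = seeds[pairs[1, ]],
                                         seed_b = seeds[pairs[2, ]],
                                         distance = pair_dist,
                                         stringsAsFactors = FALSE),
                 seeds = seeds),
            class = "seed_subnetwork")
}

#' @export
print.seed_subnetwork <- function(x, ...) {
  cat(sprintf("Seed shortest-path subnetwork: %d nodes (%d seeds), %d edges; top BC: %s\n",
              length(x$nodes), length(x$seeds), igraph::ecount(x$graph),
              x$bc_ranking$node[1]))
  invisible(x)
}

#' Enumerate all distinct shortest paths between two nodes
#'
#' Explicit predecessor-DAG enumeration: a breadth-first search from `from`
#' records, for every node at distance d(to) or less, the neighbours one step
#' closer to `from`; paths are then collected by backtracking from `to`. The
#' number of paths is counted first by dynamic programming and the
#' enumeration aborts with an error if it exceeds `cap` (path counts can
#' explode on pathological graphs).
#'
#' @param net an `igraph` network.
#' @param from,to node names.
#' @param cap maximum number of paths to enumerate (default `1e5`).
#' @return list of character vectors, each a shortest path from `from` to
#'   `to` (inclusive).
#' @export
enumerate_shortest_paths <- function(net, from, to, cap = 1e5) {
  nodes <- igraph::V(net)$name
  if (!from %in% nodes || !to %in% nodes) {
    stop("from/to must be nodes of the network", call. = FALSE)
  }
  if (from == to) return(list(from))
  adj <- igraph::as_adj_list(net, mode = "all")
  adj <- lapply(adj, function(v) nodes[as.integer(v)])
  names(adj) <- nodes

  dist <- stats::setNames(rep(Inf, length(nodes)), nodes)
  dist[from] <- 0
  frontier <- from
  while (length(frontier) > 0L && !is.finite(dist[to])) {
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    nxt <- nxt[!is.finite(dist[nxt])]
    dist[nxt] <- dist[frontier[1]] + 1
    frontier <- nxt
  }
  if (!is.finite(dist[to])) stop("nodes are not connected", call. = FALSE)

  preds <- lapply(nodes, function(v) {
    if (!is.finite(dist[v]) || dist[v] > dist[to]) return(character())
    nb <- adj[[v]]
    nb[dist[nb] == dist[v] - 1]
  })
  names(preds) <- nodes

  # path count by DP over increasing distance
  sigma <- stats::setNames(rep(0, length(nodes)), nodes)
  sigma[from] <- 1
  for (dd in seq_len(dist[to])) {
    at <- nodes[is.finite(dist) & dist == dd & dist <= dist[to]]
    for (v in at) sigma[v] <- sum(sigma[preds[[v]]])
  }
  if (sigma[to] > cap) {
    stop("shortest-path count ", sigma[to], " exceeds cap ", cap, call. = FALSE)
  }

  backtrack <- function(v) {
    if (v == from) return(list(from))
    out <- list()
    for (p in preds[[v]]) {
      for (path in backtrack(p)) out[[length(out) + 1L]] <- c(path, v)
    }
    out
  }
  backtrack(to)
}

#' Composition of a subnetwork relative to seed and high-BC sets
#'
#' Partitions the subnetwork's nodes into four categories: both seed and
#' high-BC, seed only, high-BC only, and neither; the counts always sum to
#' the subnetwork size.
#'
#' @param subnet_nodes character vector of subnetwork node names (or a
#'   `seed_subnetwork`).
#' @param seeds character vector of seed symbols.
#' @param high_bc character vector of high-betweenness (backbone) node names.
#' @return named integer vector with entries `seed_and_high_bc`, `seed_only`,
#'   `high_bc_only`, `other` and attribute `total`.
#' @export
subnetwork_composition <- function(subnet_nodes, seeds, high_bc) {
  if (inherits(subnet_nodes, "seed_subnetwork")) subnet_nodes <- subnet_nodes$nodes
  if (is.data.frame(seeds)) seeds <- seeds$symbol
  in_seed <- subnet_nodes %in% seeds
  in_bc <- subnet_nodes %in% high_bc
  out <- c(seed_and_high_bc = sum(in_seed & in_bc),
           seed_only = sum(in_seed & !in_bc),
           high_bc_only = sum(!in_seed & in_bc),
           other = sum(!in_seed & !in_bc))
  attr(out, "total") <- length(subnet_nodes)
  out
}
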