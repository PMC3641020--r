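# Per-node centralities (degree k, betweenness BC, closeness CC) and global
# network statistics (N, E, <k>, diameter, mean shortest path length).
#
# BC uses the undirected pair normalization 2/((N-1)(N-2)) with endpoints
# excluded, so the star centre scores exactly 1; CC is (N-1)/sum of
# distances. Shortest paths are unweighted throughout: interaction scores act
# only as an inclusion filter upstream, never as edge lengths.

assert_connected <- function(net, what) {
  if (!igraph::is_connected(net)) {
    stop(what, " requires a connected network; extract the giant component ",
         "first (see decompose_components())", call. = FALSE)
  }
}

#' Node degrees
#'
#' @param net an `igraph` network.
#' @return named integer vector, node name -> number of incident edges.
#' @export
node_degree <- function(net) {
  igraph::degree(net, loops = FALSE)
}

#' Normalized betweenness centrality
#'
#' For each node v, the sum over unordered pairs (s, t), s != v != t, of the
#' fraction of distinct shortest s-t paths passing through v, scaled by
#' 2/((N-1)(N-2)) so values lie in \[0, 1\] (a star centre scores 1).
#'
#' @param net a connected `igraph` network.
#' @return named numeric vector of betweenness values.
#' @export
node_betweenness <- function(net) {
  assert_connected(net, "betweenness")
  n <- igraph::vcount(net)
  if (n < 3L) {
    return(stats::setNames(rep(0, n), igraph::V(net)$name))
  }
  igraph::betweenness(net, directed = FALSE, weights = NA, normalized = TRUE)
}

#' Closeness centrality
#'
#' CC(v) = (N-1) / sum of shortest-path distances from v to every other node.
#'
#' @param net a connected `igraph` network with at least 2 nodes.
#' @return named numeric vector of closeness values in \[0, 1\].
#' @export
node_closeness <- function(net) {
  assert_connected(net, "closeness")
  if (igraph::vcount(net) < 2L) {
    stop("closeness needs at least 2 nodes", call. = FALSE)
  }
  igraph::closeness(net, weights = NA, normalized = TRUE)
}

#' Combined per-node centrality table
#'
#' @param net a connected `igraph` network.
#' @return `data.frame` with columns `node`, `degree`, `bc`, `cc`, sorted by
#'   `bc` descending then node name (deterministic report order).
#' @export
node_centralities <- function(net) {
  assert_connected(net, "centrality analysis")
  k <- node_degree(net)
  bc <- node_betweenness(net)
  cc <- node_closeness(net)
  nodes <- igraph::V(net)$name
  out <- data.frame(node = nodes,
                    degree = as.integer(k[nodes]),
                    bc = as.numeric(bc[nodes]),
                    cc = as.numeric(cc[nodes]),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$bc, out$node), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Global network statistics
#'
#' Node count N, edge count E, average degree `<k> = 2E/N`, diameter (the
#' longest shortest path, in integer steps) and mean shortest path length
#' (mean pairwise distance over unordered node pairs, self-distances
#' excluded).
#'
#' @param net a connected `igraph` network with at least 2 nodes.
#' @return a `network_stats` list: `n_nodes`, `n_edges`, `avg_degree`,
#'   `diameter`, `mspl`.
#' @export
global_stats <- function(net) {
  assert_connected(net, "global statistics")
  n <- igraph::vcount(net)
  if (n < 2L) stop("global statistics need at least 2 nodes", call. = FALSE)
  e <- igraph::ecount(net)
  d <- igraph::distances(net, weights = NA)
  pairwise <- d[upper.tri(d)]
  structure(list(n_nodes = n,
                 n_edges = e,
                 avg_degree = 2 * e / n,
                 diameter = as.integer(max(pairwise)),
                 mspl = mean(pairwise)),
            class = "network_stats")
}

#' @export
print.network_stats <- function(x, ...) {
  cat(sprintf("N=%d  E=%d  <k>=%.2f  diameter=%d  mspl=%.2f\n",
              x$n_nodes, x$n_edges, x$avg_degree, x$diameter, x$mspl))
  invisible(x)
}
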