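# Shared fixtures: small hand-built graphs and a compact synthetic-study
# configuration used by several test files.

# igraph from a character edge list, optionally with extra isolated nodes
mk_graph <- function(edges, extra_nodes = character()) {
  nodes <- sort(unique(c(edges$id_a, edges$id_b, extra_nodes)))
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = nodes, seed = FALSE))
  g
}

edge_df <- function(a, b, score = 900) {
  data.frame(id_a = a, id_b = b, score = score, stringsAsFactors = FALSE)
}

path_graph <- function(labels) {
  edge_df(labels[-length(labels)], labels[-1])
}

# seeded Erdos-Renyi edge table, conditioned on connectedness
random_connected_edges <- function(n, p, seed) {
  set.seed(seed)
  nodes <- sprintf("N%02d", seq_len(n))
  repeat {
    pairs <- utils::combn(nodes, 2)
    keep <- stats::runif(ncol(pairs)) < p
    if (!any(keep)) next
    edges <- edge_df(pairs[1, keep], pairs[2, keep])
    adj <- bf_adjacency(edges, nodes)
    if (length(bf_component_of(adj, 1)) == n) {
      return(list(nodes = nodes, edges = edges, adj = adj))
    }
  }
}

# compact planted-bridge study configuration (the parameter-recovery scale)
small_study_cfg <- function(rng_seed = 7) {
  synthetic_config(n_background = 120, attachment_edges = 2, n_modules = 2,
                   module_size = 12, n_anchors = 8, n_seeds = 20,
                   seed_in_giant_fraction = 0.9, rng_seed = rng_seed)
}
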