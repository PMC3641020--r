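# Brute-force oracles, written against a plain adjacency matrix with no
# graph library: BFS distances, explicit enumeration of all shortest paths,
# and betweenness/closeness computed from first principles. Used to check
# the package's centrality and path machinery independently.

# adjacency matrix from an edge data.frame (id_a, id_b) over `nodes`
bf_adjacency <- function(edges, nodes) {
  n <- length(nodes)
  adj <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(edges))) {
    a <- edges$id_a[i]; b <- edges$id_b[i]
    adj[a, b] <- TRUE
    adj[b, a] <- TRUE
  }
  adj
}

# single-source BFS distances (Inf where unreachable)
bf_dist_from <- function(adj, s) {
  n <- nrow(adj)
  d <- rep(Inf, n)
  d[s] <- 0
  frontier <- s
  while (length(frontier) > 0) {
    nxt <- integer()
    for (v in frontier) {
      nb <- which(adj[v, ] & !is.finite(d))
      d[nb] <- d[v] + 1
      nxt <- c(nxt, nb)
    }
    frontier <- unique(nxt)
  }
  d
}

bf_dist_matrix <- function(adj) {
  t(vapply(seq_len(nrow(adj)), function(s) bf_dist_from(adj, s),
           numeric(nrow(adj))))
}

# every shortest path from s to t, as integer index vectors
bf_all_shortest_paths <- function(adj, s, t, d = NULL) {
  if (is.null(d)) d <- bf_dist_from(adj, s)
  if (!is.finite(d[t])) return(list())
  if (s == t) return(list(s))
  walk <- function(v) {
    if (v == s) return(list(s))
    preds <- which(adj[v, ] & d == d[v] - 1)
    out <- list()
    for (p in preds) {
      for (path in walk(p)) out[[length(out) + 1]] <- c(path, v)
    }
    out
  }
  walk(t)
}

# normalized betweenness by explicit enumeration of every shortest path
bf_betweenness <- function(adj) {
  n <- nrow(adj)
  raw <- rep(0, n)
  if (n >= 3) {
    for (s in 1:(n - 1)) {
      d <- bf_dist_from(adj, s)
      for (t in (s + 1):n) {
        paths <- bf_all_shortest_paths(adj, s, t, d)
        if (length(paths) == 0) next
        for (path in paths) {
          interior <- setdiff(path, c(s, t))
          raw[interior] <- raw[interior] + 1 / length(paths)
        }
      }
    }
    raw <- raw * 2 / ((n - 1) * (n - 2))
  }
  names(raw) <- rownames(adj)
  raw
}

bf_closeness <- function(adj) {
  dm <- bf_dist_matrix(adj)
  out <- (nrow(adj) - 1) / rowSums(dm)
  names(out) <- rownames(adj)
  out
}

# reachable node set by brute-force closure (component oracle)
bf_component_of <- function(adj, s) {
  members <- s
  repeat {
    nb <- which(apply(adj[members, , drop = FALSE], 2, any))
    grown <- union(members, nb)
    if (length(grown) == length(members)) return(sort(members))
    members <- grown
  }
}
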