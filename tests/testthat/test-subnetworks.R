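test_that("top-fraction selection applies the ceiling rule and keeps boundary ties", {
  vals <- setNames(seq_len(535), sprintf("N%03d", seq_len(535)))
  expect_equal(nrow(select_top_fraction(vals, 535, 0.05)), 27)  # ceil(26.75)

  vals100 <- setNames(runif(100), sprintf("N%03d", 1:100))
  expect_equal(nrow(select_top_fraction(vals100, 100, 0.05)), 5)

  vals40 <- setNames(runif(40), sprintf("N%02d", 1:40))
  expect_equal(nrow(select_top_fraction(vals40, 40, 0.05)), 2)  # ceil(2.0)

  # ties at the boundary inflate the selection
  tied <- setNames(c(10, 9, 5, 5, 5, 1), paste0("T", 1:6))
  sel <- select_top_fraction(tied, 6, 0.5)  # m = 3 but three nodes share rank 3
  expect_equal(nrow(sel), 5)
  expect_true(attr(sel, "tie_inflated"))
  expect_equal(attr(sel, "m_nominal"), 3)
  # deterministic order: score desc then name
  expect_equal(sel$node, c("T1", "T2", "T3", "T4", "T5"))
})

test_that("backbone extraction returns the induced top-BC subgraph", {
  # 20-node star: fraction 0.05 keeps the single top node, edgeless backbone
  star <- mk_graph(edge_df(rep("HUB", 19), sprintf("L%02d", 1:19)))
  bb <- extract_backbone(star, fraction = 0.05)
  expect_equal(bb$cutoff_count, 1)
  expect_equal(igraph::ecount(bb$graph), 0)

  # members are sorted by BC descending and induce the backbone graph
  case <- random_connected_edges(10, 0.35, seed = 501)
  g <- mk_graph(case$edges)
  bb2 <- extract_backbone(g, fraction = 0.3)
  expect_true(all(diff(bb2$members$score) <= 0))
  expect_setequal(igraph::V(bb2$graph)$name, bb2$members$node)
})

test_that("backbone membership is invariant under BC-preserving relabelling", {
  case <- random_connected_edges(10, 0.3, seed = 502)
  g <- mk_graph(case$edges)
  perm <- setNames(sprintf("Z%02d", sample(10)), igraph::V(g)$name)
  rel <- case$edges
  rel$id_a <- unname(perm[rel$id_a]); rel$id_b <- unname(perm[rel$id_b])
  g2 <- mk_graph(rel)
  bb1 <- extract_backbone(g, fraction = 0.3)$members$node
  bb2 <- extract_backbone(g2, fraction = 0.3)$members$node
  expect_setequal(unname(perm[bb1]), bb2)
})

test_that("key-node classification partitions nodes into the four categories", {
  # star: centre is hub-bottleneck, leaves nonhub-nonbottleneck
  leaves <- paste0("L", 1:9)
  star <- mk_graph(edge_df(rep("HUB", 9), leaves))
  cls <- classify_key_nodes(node_degree(star), node_betweenness(star),
                            fraction = 0.1)
  expect_equal(cls$hub_bottleneck, "HUB")
  expect_equal(sum(cls$counts), 10)
  expect_equal(unname(cls$counts["nonhub-nonbottleneck"]), 9)

  # coinciding rankings: bottleneck-only and hub-only sets are empty
  deg <- setNames(c(5, 4, 3, 2, 1), paste0("A", 1:5))
  cls2 <- classify_key_nodes(deg, deg / 10, fraction = 0.4)
  expect_length(cls2$bottleneck_only, 0)
  expect_length(cls2$hub_only, 0)

  # random graph: the four counts always sum to N
  case <- random_connected_edges(10, 0.3, seed = 503)
  g <- mk_graph(case$edges)
  cls3 <- classify_key_nodes(node_degree(g), node_betweenness(g), fraction = 0.25)
  expect_equal(sum(cls3$counts), 10)
  expect_error(classify_key_nodes(deg, deg[-1]), "same node set")
})

test_that("seed subnetwork keeps every node on any shortest seed path", {
  # square A-B-D / A-C-D with seeds {A,D}: both length-2 paths kept
  sq <- mk_graph(edge_df(c("A", "B", "A", "C"), c("B", "D", "C", "D")))
  sub <- seed_shortest_path_subnetwork(sq, c("A", "D"))
  expect_setequal(sub$nodes, c("A", "B", "C", "D"))

  # adjacent seeds: the edge is the path
  sub2 <- seed_shortest_path_subnetwork(sq, c("A", "B"))
  expect_setequal(sub2$nodes, c("A", "B"))

  # a node off every shortest path is excluded
  g <- mk_graph(rbind(path_graph(c("S1", "M", "S2")),
                      path_graph(c("S1", "X", "Y", "S2"))))
  sub3 <- seed_shortest_path_subnetwork(g, c("S1", "S2"))
  expect_setequal(sub3$nodes, c("S1", "M", "S2"))
})

test_that("seed subnetwork members and distances match the enumeration oracle", {
  for (s in 1:5) {
    case <- random_connected_edges(9, 0.3, seed = 600 + s)
    g <- mk_graph(case$edges)
    nodes <- igraph::V(g)$name
    seeds <- sample(nodes, 3)
    sub <- seed_shortest_path_subnetwork(g, seeds)

    # oracle: union of explicitly enumerated shortest-path vertices
    idx <- setNames(seq_along(rownames(case$adj)), rownames(case$adj))
    expected <- character()
    for (pr in utils::combn(sort(seeds), 2, simplify = FALSE)) {
      paths <- bf_all_shortest_paths(case$adj, idx[[pr[1]]], idx[[pr[2]]])
      expected <- union(expected, rownames(case$adj)[unlist(paths)])
    }
    expect_setequal(sub$nodes, expected)

    # distance preservation: seed-pair distances inside the subnetwork equal
    # those in the full graph
    din <- igraph::distances(sub$graph, v = sub$seeds, to = sub$seeds, weights = NA)
    dout <- igraph::distances(g, v = sub$seeds, to = sub$seeds, weights = NA)
    expect_equal(din, dout)

    # minimality direction: every non-seed member lies on >= 1 shortest path
    non_seed <- setdiff(sub$nodes, sub$seeds)
    for (v in non_seed) {
      on_any <- any(vapply(utils::combn(sort(seeds), 2, simplify = FALSE),
        function(pr) {
          paths <- bf_all_shortest_paths(case$adj, idx[[pr[1]]], idx[[pr[2]]])
          any(vapply(paths, function(p) idx[[v]] %in% p, TRUE))
        }, TRUE))
      expect_true(on_any)
    }
  }
})

test_that("explicit shortest-path enumeration matches the oracle and obeys its cap", {
  for (s in 1:4) {
    case <- random_connected_edges(8, 0.35, seed = 700 + s)
    g <- mk_graph(case$edges)
    nodes <- rownames(case$adj)
    picks <- utils::combn(sample(nodes, 4), 2)
    for (i in seq_len(ncol(picks))) {
      a <- picks[1, i]; b <- picks[2, i]
      got <- enumerate_shortest_paths(g, a, b)
      idx <- setNames(seq_along(nodes), nodes)
      want <- bf_all_shortest_paths(case$adj, idx[[a]], idx[[b]])
      want <- lapply(want, function(p) nodes[p])
      canon <- function(paths) sort(vapply(paths, paste, "", collapse = ">"))
      expect_equal(canon(got), canon(want))
    }
  }
  # ladder of squares: path count doubles per rung, tiny cap must refuse
  ladder <- rbind(edge_df(c("A", "A", "B1", "C1"), c("B1", "C1", "D", "D")),
                  edge_df(c("D", "D", "E1", "F1"), c("E1", "F1", "G", "G")))
  lg <- mk_graph(ladder)
  expect_length(enumerate_shortest_paths(lg, "A", "G"), 4)
  expect_error(enumerate_shortest_paths(lg, "A", "G", cap = 3), "cap")
})

test_that("subnetwork composition partitions the node set", {
  nodes <- sprintf("N%02d", 1:12)
  comp <- subnetwork_composition(nodes, seeds = nodes[1:5],
                                 high_bc = nodes[4:8])
  expect_equal(sum(comp), 12)
  expect_equal(unname(comp["seed_and_high_bc"]), 2)
  expect_equal(unname(comp["seed_only"]), 3)
  expect_equal(unname(comp["high_bc_only"]), 3)
  expect_equal(unname(comp["other"]), 4)
})
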