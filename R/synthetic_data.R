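# Synthetic STRING-like interactomes with known ground truth: a scale-free
# background, dense modules joined to the rest of the graph only through a
# designated bridge node (a cut vertex, hence provably the betweenness
# maximum among candidates for module traffic), confidence scores with a
# known low-score fraction, and small detached satellite components.

#' Configuration for the synthetic interactome generator
#'
#' Defaults emulate the shape of the reference study's input: a few hundred
#' background proteins, 69 seed genes of which two sit in detached two-node
#' satellite components, a single high-betweenness bridge that is *not* a
#' seed (so it must re-enter the extended network as a neighbour), and 20%
#' of confidence scores below the 400 threshold so score filtering is always
#' exercised.
#'
#' @param n_background scale-free background node count.
#' @param attachment_edges edges per new node in the preferential-attachment
#'   background.
#' @param n_modules number of dense modules hanging off the bridge.
#' @param module_size nodes per module.
#' @param bridge_node identifier of the planted bridge.
#' @param n_anchors background nodes the bridge attaches to.
#' @param n_seeds seed-list length.
#' @param seed_in_giant_fraction fraction of seeds placed in the giant
#'   region; the remainder go one-per-satellite.
#' @param n_satellites number of detached two-node components.
#' @param score_low_fraction fraction of all edges scored below
#'   `score_threshold`.
#' @param score_threshold confidence threshold the low/high score mixture is
#'   anchored to (default 400).
#' @param include_bridge_seed make the bridge itself a seed (default FALSE,
#'   reproducing the omitted-central-gene re-entry phenomenon).
#' @param rng_seed integer RNG seed; generation is deterministic given it.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_background = 500, attachment_edges = 3,
                             n_modules = 2, module_size = 25,
                             bridge_node = "BRG1", n_anchors = 15,
                             n_seeds = 69, seed_in_giant_fraction = 67 / 69,
                             n_satellites = 2, score_low_fraction = 0.2,
                             score_threshold = 400,
                             include_bridge_seed = FALSE, rng_seed = 1) {
  cfg <- list(n_background = n_background, attachment_edges = attachment_edges,
              n_modules = n_modules, module_size = module_size,
              bridge_node = normalize_symbol(bridge_node),
              n_anchors = n_anchors, n_seeds = n_seeds,
              seed_in_giant_fraction = seed_in_giant_fraction,
              n_satellites = n_satellites,
              score_low_fraction = score_low_fraction,
              score_threshold = score_threshold,
              include_bridge_seed = include_bridge_seed,
              rng_seed = as.integer(rng_seed))
  with(cfg, {
    stopifnot(n_background >= 10, attachment_edges >= 1, n_modules >= 0,
              module_size >= 2 || n_modules == 0, n_anchors >= 1,
              n_seeds >= 1, n_satellites >= 0,
              seed_in_giant_fraction > 0, seed_in_giant_fraction <= 1,
              score_low_fraction >= 0, score_low_fraction < 1)
  })
  structure(cfg, class = "synthetic_config")
}

#' Generate a synthetic interactome with known ground truth
#'
#' Construction: (a) a scale-free background by preferential attachment;
#' (b) `n_modules` cliques whose only connection to the rest of the graph is
#' the bridge node (adjacent to every module member), so every shortest path
#' between a module node and any non-module node, and between two modules,
#' traverses the bridge; (c) the bridge attached to `n_anchors`
#' moderate-degree background nodes at spread degree ranks (so the module
#' traffic it carries is split across anchors instead of reinforcing an
#' existing hub, and the bridge additionally shortcuts background
#' geodesics); (d) `n_satellites` detached two-node
#' components; (e) integer confidence scores, with `score_low_fraction` of
#' all edges drawn below `score_threshold` -- structural edges (module,
#' bridge-incident, satellite, and a background spanning tree) always score
#' high so filtering at the threshold never severs the designed giant
#' region. A verification pass asserts the cut-vertex property on the
#' high-confidence graph.
#'
#' @param cfg a [synthetic_config()].
#' @return list with `interactions` (`id_a`, `id_b`, `score`) and `truth`
#'   (bridge, anchors, module membership, satellites, background ids,
#'   giant-region ids, threshold).
#' @export
generate_interactome <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$rng_seed)
  bg_names <- sprintf("G%04d", seq_len(cfg$n_background))
  bg <- igraph::sample_pa(cfg$n_background, m = cfg$attachment_edges,
                          directed = FALSE)
  bg <- igraph::simplify(bg)
  igraph::V(bg)$name <- bg_names
  el_bg <- igraph::as_edgelist(bg)
  # a spanning tree of the background stays high-confidence
  st <- igraph::mst(bg)
  el_st <- igraph::as_edgelist(st)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  structural <- key(el_st[, 1], el_st[, 2])

  edges <- data.frame(id_a = el_bg[, 1], id_b = el_bg[, 2],
                      stringsAsFactors = FALSE)
  modules <- list()
  if (cfg$n_modules > 0) {
    for (mi in seq_len(cfg$n_modules)) {
      mem <- sprintf("M%d_%02d", mi, seq_len(cfg$module_size))
      modules[[paste0("module", mi)]] <- mem
      pr <- utils::combn(mem, 2)
      edges <- rbind(edges,
                     data.frame(id_a = pr[1, ], id_b = pr[2, ],
                                stringsAsFactors = FALSE),
                     data.frame(id_a = cfg$bridge_node, id_b = mem,
                                stringsAsFactors = FALSE))
      structural <- c(structural, key(pr[1, ], pr[2, ]),
                      key(cfg$bridge_node, mem))
    }
  }
  # Anchors are moderate-degree nodes at spread degree ranks: attaching the
  # bridge to the top hubs would let a hub inherit the module traffic on top
  # of its own and contest the bridge's betweenness maximum; mid-rank anchors
  # split the module traffic while the bridge carries all of it.
  by_degree <- bg_names[order(-igraph::degree(bg), bg_names)]
  ranks <- unique(pmax(1L, floor(cfg$n_background *
                                   seq(0.25, 0.6, length.out = cfg$n_anchors))))
  anchors <- by_degree[ranks]
  if (cfg$n_modules > 0) {
    edges <- rbind(edges, data.frame(id_a = cfg$bridge_node, id_b = anchors,
                                     stringsAsFactors = FALSE))
    structural <- c(structural, key(cfg$bridge_node, anchors))
  }

  satellites <- list()
  if (cfg$n_satellites > 0) {
    for (si in seq_len(cfg$n_satellites)) {
      pair <- sprintf("SAT%d%s", si, c("A", "B"))
      satellites[[si]] <- pair
      edges <- rbind(edges, data.frame(id_a = pair[1], id_b = pair[2],
                                       stringsAsFactors = FALSE))
      structural <- c(structural, key(pair[1], pair[2]))
    }
  }

  n_edges <- nrow(edges)
  ekey <- key(edges$id_a, edges$id_b)
  candidates <- which(!ekey %in% structural)
  n_low <- min(round(cfg$score_low_fraction * n_edges), length(candidates))
  low_idx <- if (n_low > 0) sample(candidates, n_low) else integer()
  score <- round(stats::runif(n_edges, cfg$score_threshold, 999))
  score[low_idx] <- round(stats::runif(n_low, 150, cfg$score_threshold - 1))
  interactions <- clean_interactions(
    data.frame(id_a = edges$id_a, id_b = edges$id_b, score = score,
               stringsAsFactors = FALSE))

  truth <- list(bridge_node = cfg$bridge_node,
                anchors = anchors,
                modules = modules,
                satellites = satellites,
                background = bg_names,
                giant_region = c(bg_names, unlist(modules, use.names = FALSE),
                                 if (cfg$n_modules > 0) cfg$bridge_node),
                score_threshold = cfg$score_threshold)

  if (cfg$n_modules > 0) verify_bridge_cut(interactions, truth)
  list(interactions = interactions, truth = truth)
}

# Assert the construction guarantee: on the high-confidence graph, removing
# the bridge disconnects every module node from the background.
verify_bridge_cut <- function(interactions, truth) {
  hi <- interactions[interactions$score >= truth$score_threshold, ]
  g <- igraph::graph_from_data_frame(hi[, c("id_a", "id_b")], directed = FALSE)
  module_nodes <- unlist(truth$modules, use.names = FALSE)
  g2 <- igraph::delete_vertices(g, truth$bridge_node)
  comp <- igraph::components(g2)
  mem <- comp$membership[module_nodes]
  bg_mem <- comp$membership[intersect(truth$background, igraph::V(g2)$name)]
  if (any(mem %in% bg_mem)) {
    stop("infeasible module wiring: a module connects to the background ",
         "without the bridge", call. = FALSE)
  }
  invisible(TRUE)
}

#' Sample a seed list from a synthetic interactome
#'
#' Places a `seed_in_giant_fraction` share of the seeds in the designed giant
#' region and one seed in each of the remaining satellites. The giant-region
#' seeds always include two bridge anchors (when available) and two members
#' of every module, which keeps the bridge reachable in the extended network
#' even after any single seed is omitted; the rest are sampled uniformly
#' from the background. The bridge itself is excluded unless
#' `include_bridge_seed`.
#'
#' When the interaction table is supplied, the sampler additionally verifies
#' that every giant-region seed really joins the giant component of the
#' extended network built at the configured threshold (a peripheral
#' background seed can otherwise detach, because its route to the core may
#' run through nodes outside the seed neighbourhoods), deterministically
#' resampling any that do not.
#'
#' @param cfg the [synthetic_config()] used for generation.
#' @param truth the ground-truth list from [generate_interactome()].
#' @param interactions optional interaction table from the same generation;
#'   enables the giant-membership repair pass.
#' @return seed `data.frame` (`symbol`, `description`).
#' @export
generate_seed_list <- function(cfg, truth, interactions = NULL) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$rng_seed + 1L)
  n_giant <- round(cfg$seed_in_giant_fraction * cfg$n_seeds)
  n_sat <- cfg$n_seeds - n_giant
  if (n_sat > length(truth$satellites)) {
    stop("not enough satellite components for ", n_sat, " satellite seeds",
         call. = FALSE)
  }
  sat_seeds <- vapply(truth$satellites[seq_len(n_sat)], `[`, "", 1L)

  guaranteed <- unique(c(truth$anchors[seq_len(min(2L, length(truth$anchors)))],
                         unlist(lapply(truth$modules, function(m) {
                           sample(m, min(2L, length(m)))
                         }), use.names = FALSE)))
  if (cfg$include_bridge_seed) guaranteed <- c(guaranteed, truth$bridge_node)
  if (length(guaranteed) > n_giant) {
    stop("n_seeds too small for the guaranteed anchor/module seeds",
         call. = FALSE)
  }
  pool <- setdiff(truth$background, c(guaranteed, truth$bridge_node))
  extra <- sample(pool, n_giant - length(guaranteed))
  pool <- setdiff(pool, extra)

  if (!is.null(interactions)) {
    # repair pass: replace giant-region seeds that fail to join the giant
    for (iter in 1:100) {
      symbols <- c(guaranteed, extra, sat_seeds)
      net <- suppressWarnings(
        build_extended_network(symbols, interactions,
                               min_score = cfg$score_threshold,
                               keep_missing_seeds = TRUE))
      giant <- decompose_components(net)$giant
      bad <- setdiff(c(guaranteed, extra), giant)
      if (length(bad) == 0L) break
      if (length(pool) < length(bad)) {
        stop("cannot place all seeds in the giant region", call. = FALSE)
      }
      fresh <- sample(pool, length(bad))
      pool <- setdiff(pool, fresh)
      extra <- c(setdiff(extra, bad), fresh)
    }
    if (length(setdiff(c(guaranteed, extra), giant)) > 0L) {
      stop("giant-membership repair did not converge", call. = FALSE)
    }
  }
  symbols <- c(sort(c(guaranteed, extra)), sat_seeds)
  kind <- ifelse(symbols %in% truth$anchors, "bridge anchor (background hub)",
          ifelse(symbols %in% unlist(truth$modules, use.names = FALSE), "module member",
          ifelse(symbols %in% sat_seeds, "satellite component member",
                 "background node")))
  data.frame(symbol = symbols, description = paste("synthetic", kind),
             stringsAsFactors = FALSE)
}
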