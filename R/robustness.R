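# Leave-k-out seed-omission validation: enumerate test networks built from
# reduced seed sets, rebuild each, and summarize (a) how often each node has
# the largest betweenness and (b) how well the top-M BC set of each test
# network agrees with the reference backbone.

#' Number of omitted-seed combinations
#'
#' Bookkeeping helper for the omission protocol: the number of ways to omit
#' `k` genes out of `n`, either as ordered selections `n (n-1) ... (n-k+1)`
#' or as unordered subsets `choose(n, k)`.
#'
#' @param n number of seed genes.
#' @param k number omitted.
#' @param ordered count ordered selections (default) or unordered subsets.
#' @return a number.
#' @export
omission_combination_count <- function(n, k, ordered = TRUE) {
  stopifnot(k >= 0, k <= n)
  if (ordered) prod(seq(n, n - k + 1)) else choose(n, k)
}

#' Build a seed-omission plan
#'
#' The protocol omits from 1 to `k_max` seeds per test network. For k = 1
#' every seed is omitted once (one configuration per seed). For k = 2 the
#' central gene is paired with every other seed. For k >= 3 each of
#' `draws_per_k` configurations is the central gene plus a uniform sample
#' (without replacement, independent across draws) of k - 1 of the remaining
#' seeds; the central gene is omitted in every one. With 69 seeds,
#' `k_max = 7` and 30 draws per k this yields 69 + 68 + 5 * 30 = 287
#' configurations.
#'
#' @param seeds character vector of seed symbols or a seed `data.frame`.
#' @param central the central gene under scrutiny (must be a seed).
#' @param k_max largest number of omitted seeds (default 7, about 10% of 69).
#' @param draws_per_k random configurations for each k >= 3 (default 30).
#' @param rng_seed integer RNG seed; the plan is deterministic given it.
#' @return an `omission_plan`: list with `groups` (named by k, each a list of
#'   omitted-seed character vectors), `central`, `draws_per_k`, `rng_seed`,
#'   `n_configurations`, `seeds`.
#' @export
build_omission_plan <- function(seeds, central, k_max = 7, draws_per_k = 30,
                                rng_seed = 1) {
  if (is.data.frame(seeds)) seeds <- seeds$symbol
  seeds <- normalize_symbol(seeds)
  central <- normalize_symbol(central)
  if (!central %in% seeds) {
    stop("central gene ", central, " is not among the seeds", call. = FALSE)
  }
  if (k_max < 1 || k_max > length(seeds)) {
    stop("k_max must lie in [1, number of seeds]", call. = FALSE)
  }
  others <- setdiff(seeds, central)
  groups <- list()
  groups[["1"]] <- lapply(seeds, function(s) s)
  if (k_max >= 2) {
    groups[["2"]] <- lapply(others, function(s) sort(c(central, s)))
  }
  if (k_max >= 3) {
    set.seed(rng_seed)
    for (k in 3:k_max) {
      groups[[as.character(k)]] <- lapply(seq_len(draws_per_k), function(i) {
        sort(c(central, sample(others, k - 1)))
      })
    }
  }
  groups <- groups[as.character(seq_len(min(k_max, length(groups))))]
  structure(list(groups = groups,
                 central = central,
                 draws_per_k = draws_per_k,
                 rng_seed = rng_seed,
                 n_configurations = sum(lengths(groups)),
                 seeds = seeds),
            class = "omission_plan")
}

#' @export
print.omission_plan <- function(x, ...) {
  cat(sprintf("Omission plan: %d configurations (central %s); group sizes: %s\n",
              x$n_configurations, x$central,
              paste(lengths(x$groups), collapse = ", ")))
  invisible(x)
}

#' Run one seed-omission test network
#'
#' Rebuilds the extended network from the remaining seeds (omitted genes may
#' re-enter as neighbours of other seeds -- the central gene can top the
#' betweenness ranking even while omitted), extracts the giant component,
#' computes betweenness, and records the largest-BC node and the overlap of
#' the top-M BC set with the reference backbone. Boundary ties in the top-M
#' set are resolved deterministically (BC descending, then node name) and the
#' set is truncated to exactly M for the accuracy ratio.
#'
#' @param omitted character vector of omitted seed symbols.
#' @param seeds full seed symbol vector (or seed `data.frame`).
#' @param interactions cleaned interaction table.
#' @param reference_backbone character vector of reference backbone node
#'   names (or a `backbone_result`).
#' @param m top-set size; defaults to the reference backbone size.
#' @param min_score,keep_missing_seeds passed to [build_extended_network()].
#' @return list with `omitted`, `top_bc_node`, `top_m`, `accuracy`,
#'   `giant_size`.
#' @export
run_test_network <- function(omitted, seeds, interactions, reference_backbone,
                             m = NULL, min_score = 400,
                             keep_missing_seeds = FALSE) {
  if (inherits(reference_backbone, "backbone_result")) {
    reference_backbone <- reference_backbone$members$node
  }
  if (is.null(m)) m <- length(reference_backbone)
  if (is.data.frame(seeds)) seeds <- seeds$symbol
  seeds <- normalize_symbol(seeds)
  remaining <- setdiff(seeds, normalize_symbol(omitted))
  if (length(remaining) == 0L) stop("all seeds omitted", call. = FALSE)
  net <- withCallingHandlers(
    build_extended_network(remaining, interactions, min_score = min_score,
                           keep_missing_seeds = keep_missing_seeds),
    seednet_missing_seeds = function(w) invokeRestart("muffleWarning"))
  giant <- decompose_components(net)$giant_graph
  bc <- node_betweenness(giant)
  ord <- order(-bc, names(bc))
  ranked <- names(bc)[ord]
  m_eff <- min(m, length(ranked))
  if (m_eff < m) {
    warning("giant component smaller than the top-set size M (", length(ranked),
            " < ", m, "); accuracy computed over the available nodes",
            call. = FALSE)
  }
  top_m <- ranked[seq_len(m_eff)]
  list(omitted = sort(omitted),
       top_bc_node = ranked[1],
       top_m = top_m,
       accuracy = length(intersect(top_m, reference_backbone)) / m_eff,
       giant_size = length(ranked))
}

#' Run the full seed-omission robustness protocol
#'
#' Computes the reference backbone from the full seed set (unless supplied),
#' then runs every configuration of the omission plan through
#' [run_test_network()] with M frozen at the reference backbone's size.
#'
#' @param plan an `omission_plan` from [build_omission_plan()].
#' @param seeds full seed vector or seed `data.frame`.
#' @param interactions cleaned interaction table.
#' @param reference_backbone optional precomputed `backbone_result` or node
#'   vector; computed from the full-seed run when `NULL`.
#' @param fraction backbone cutoff fraction used when computing the
#'   reference, default 0.05.
#' @param min_score,keep_missing_seeds passed to [build_extended_network()].
#' @return a `robustness_result`: list with `detail` (one row per test
#'   network: `k`, `draw`, `omitted`, `top_bc_node`, `accuracy`,
#'   `giant_size`), `reference_backbone`, `m`, `plan`.
#' @export
run_robustness <- function(plan, seeds, interactions, reference_backbone = NULL,
                           fraction = 0.05, min_score = 400,
                           keep_missing_seeds = FALSE) {
  stopifnot(inherits(plan, "omission_plan"))
  if (is.null(reference_backbone)) {
    net <- build_extended_network(seeds, interactions, min_score = min_score,
                                  keep_missing_seeds = keep_missing_seeds)
    giant <- decompose_components(net)$giant_graph
    reference_backbone <- extract_backbone(giant, fraction = fraction)
  }
  ref_nodes <- if (inherits(reference_backbone, "backbone_result")) {
    reference_backbone$members$node
  } else reference_backbone
  m <- length(ref_nodes)

  rows <- list()
  for (kchr in names(plan$groups)) {
    cfgs <- plan$groups[[kchr]]
    for (i in seq_along(cfgs)) {
      res <- run_test_network(cfgs[[i]], seeds, interactions, ref_nodes, m = m,
                              min_score = min_score,
                              keep_missing_seeds = keep_missing_seeds)
      rows[[length(rows) + 1L]] <- data.frame(
        k = as.integer(kchr), draw = i,
        omitted = paste(res$omitted, collapse = ";"),
        top_bc_node = res$top_bc_node,
        accuracy = res$accuracy,
        giant_size = res$giant_size,
        stringsAsFactors = FALSE)
    }
  }
  structure(list(detail = do.call(rbind, rows),
                 reference_backbone = ref_nodes,
                 m = m,
                 plan = plan),
            class = "robustness_result")
}

#' Aggregate per-group robustness rows into a summary
#'
#' Takes a per-k table (columns: `k`, one frequency column per candidate
#' largest-BC node, `accuracy`, `n_networks`) and computes the summary row:
#' per-node frequency totals (column sums), the overall accuracy as the
#' *unweighted* mean of the per-group accuracies, the network-weighted mean
#' as a labelled alternative, and the total network count.
#'
#' @param per_k per-group `data.frame` as described above.
#' @return list with `frequency_totals` (named numeric),
#'   `overall_accuracy` (unweighted group mean),
#'   `overall_accuracy_weighted` (network-weighted mean) and `n_total`.
#' @export
aggregate_robustness_groups <- function(per_k) {
  stopifnot(all(c("k", "accuracy", "n_networks") %in% names(per_k)))
  node_cols <- setdiff(names(per_k), c("k", "accuracy", "n_networks"))
  totals <- colSums(per_k[, node_cols, drop = FALSE])
  list(frequency_totals = totals,
       overall_accuracy = mean(per_k$accuracy),
       overall_accuracy_weighted = sum(per_k$accuracy * per_k$n_networks) /
         sum(per_k$n_networks),
       n_total = sum(per_k$n_networks))
}

#' Summarize a robustness run
#'
#' Per omitted-gene count k: how often each node had the largest BC, the mean
#' backbone accuracy over the group's test networks, and the group size;
#' plus the summary aggregation of [aggregate_robustness_groups()].
#'
#' @param result a `robustness_result` from [run_robustness()] (or its
#'   `detail` `data.frame`).
#' @return a `robustness_summary`: list with `per_k` (`data.frame`),
#'   `frequency_totals`, `overall_accuracy`, `overall_accuracy_weighted`,
#'   `n_total`.
#' @export
summarize_robustness <- function(result) {
  detail <- if (inherits(result, "robustness_result")) result$detail else result
  stopifnot(is.data.frame(detail), nrow(detail) > 0L)
  candidates <- sort(unique(detail$top_bc_node))
  ks <- sort(unique(detail$k))
  per_k <- do.call(rbind, lapply(ks, function(k) {
    d <- detail[detail$k == k, , drop = FALSE]
    freq <- vapply(candidates, function(nd) sum(d$top_bc_node == nd), 0L)
    row <- data.frame(k = k, t(freq), accuracy = mean(d$accuracy),
                      n_networks = nrow(d), check.names = FALSE)
    row
  }))
  rownames(per_k) <- NULL
  agg <- aggregate_robustness_groups(per_k)
  structure(c(list(per_k = per_k), agg), class = "robustness_summary")
}

#' @export
print.robustness_summary <- function(x, ...) {
  cat(sprintf("Robustness over %d test networks: overall accuracy %.5f (unweighted group mean)\n",
              x$n_total, x$overall_accuracy))
  top <- sort(x$frequency_totals, decreasing = TRUE)
  cat("Largest-BC frequency totals:",
      paste(names(top), top, sep = "=", collapse = ", "), "\n")
  invisible(x)
}
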