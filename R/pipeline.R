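# End-to-end orchestration: seed list + interaction table -> extended
# network -> giant component -> centralities -> backbone & key nodes -> seed
# shortest-path subnetwork -> seed-omission robustness, with result tables,
# optional Pajek exports, and a run manifest that makes the run reproducible.

#' Assemble a run configuration
#'
#' @param seeds path to a seed list file, or a seed `data.frame`.
#' @param interactions path to an interaction table, or an interaction
#'   `data.frame`.
#' @param output_dir directory for tables, Pajek files and the manifest;
#'   `NULL` to skip writing.
#' @param min_score interaction confidence threshold (0-1000 scale),
#'   default 400.
#' @param fraction top-fraction cutoff for backbone/hub selection,
#'   default 0.05.
#' @param central_gene central gene for the robustness protocol; `NULL`
#'   (default) uses the top-BC node of the reference giant component.
#' @param k_max,draws_per_k omission-protocol parameters (defaults 7 and 30).
#' @param rng_seed integer seed for every randomized stage.
#' @param keep_missing_seeds keep seeds absent from the table as isolated
#'   nodes.
#' @param emit_pajek write Pajek `.net` files for the extended network,
#'   giant component, backbone and seed subnetwork.
#' @param with_robustness run the omission protocol (the slow stage).
#' @return a `run_config` list.
#' @export
run_config <- function(seeds, interactions, output_dir = NULL, min_score = 400,
                       fraction = 0.05, central_gene = NULL, k_max = 7,
                       draws_per_k = 30, rng_seed = 1,
                       keep_missing_seeds = FALSE, emit_pajek = TRUE,
                       with_robustness = TRUE) {
  stopifnot(fraction > 0, fraction <= 1)
  structure(list(seeds = seeds, interactions = interactions,
                 output_dir = output_dir, min_score = min_score,
                 fraction = fraction, central_gene = central_gene,
                 k_max = k_max, draws_per_k = draws_per_k,
                 rng_seed = as.integer(rng_seed),
                 keep_missing_seeds = keep_missing_seeds,
                 emit_pajek = emit_pajek,
                 with_robustness = with_robustness),
            class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' Recognized keys mirror the arguments of [run_config()]; unknown keys are
#' rejected.
#'
#' @param path YAML file path.
#' @param ... overrides applied after reading.
#' @return a `run_config`.
#' @export
load_run_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0L) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(run_config, vals)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes: read inputs -> build extended network -> component
#' decomposition -> global statistics and centralities on the giant
#' component -> high-BC backbone and hub/bottleneck key-node tables -> seed
#' shortest-path subnetwork -> (optionally) the seed-omission robustness
#' protocol; then writes result tables, Pajek files and a manifest
#' recording the configuration and package version. Re-running with the
#' manifest's configuration reproduces the tables byte for byte.
#'
#' @param cfg a `run_config` (or a YAML path accepted by
#'   [load_run_config()]).
#' @return invisibly, the result bundle: `seeds`, `interactions`, `network`,
#'   `decomposition`, `stats`, `centralities`, `backbone`, `key_nodes`,
#'   `subnetwork`, `robustness`, `robustness_summary`, `files`.
#' @export
run_full_analysis <- function(cfg) {
  if (is.character(cfg)) cfg <- load_run_config(cfg)
  stopifnot(inherits(cfg, "run_config"))

  seeds <- stage("read_seeds", {
    if (is.character(cfg$seeds)) read_seed_list(cfg$seeds) else cfg$seeds
  })
  interactions <- stage("read_interactions", {
    if (is.character(cfg$interactions)) read_interactions(cfg$interactions)
    else clean_interactions(cfg$interactions)
  })
  network <- stage("build_extended_network",
    build_extended_network(seeds, interactions, min_score = cfg$min_score,
                           keep_missing_seeds = cfg$keep_missing_seeds))
  decomposition <- stage("decompose_components", decompose_components(network))
  giant <- decomposition$giant_graph
  stats_ <- stage("global_stats", global_stats(giant))
  centralities <- stage("centralities", node_centralities(giant))
  bc <- stats::setNames(centralities$bc, centralities$node)
  deg <- stats::setNames(centralities$degree, centralities$node)
  backbone <- stage("extract_backbone",
                    extract_backbone(giant, bc = bc, fraction = cfg$fraction))
  key_nodes <- stage("classify_key_nodes",
                     classify_key_nodes(deg, bc, igraph::vcount(giant),
                                        cfg$fraction))
  subnetwork <- stage("seed_subnetwork",
                      seed_shortest_path_subnetwork(giant, seeds))

  robustness <- NULL
  robustness_summary <- NULL
  if (isTRUE(cfg$with_robustness)) {
    central <- cfg$central_gene
    if (is.null(central)) {
      central <- centralities$node[1]
      if (!central %in% seeds$symbol) {
        # protocol requires a seed; fall back to the top-BC seed gene
        central <- centralities$node[centralities$node %in% seeds$symbol][1]
      }
    }
    plan <- stage("build_omission_plan",
                  build_omission_plan(seeds, central, k_max = cfg$k_max,
                                      draws_per_k = cfg$draws_per_k,
                                      rng_seed = cfg$rng_seed))
    robustness <- stage("run_robustness",
                        run_robustness(plan, seeds, interactions,
                                       reference_backbone = backbone,
                                       fraction = cfg$fraction,
                                       min_score = cfg$min_score,
                                       keep_missing_seeds = cfg$keep_missing_seeds))
    robustness_summary <- stage("summarize_robustness",
                                summarize_robustness(robustness))
  }

  bundle <- list(seeds = seeds, interactions = interactions, network = network,
                 decomposition = decomposition, stats = stats_,
                 centralities = centralities, backbone = backbone,
                 key_nodes = key_nodes, subnetwork = subnetwork,
                 robustness = robustness,
                 robustness_summary = robustness_summary,
                 config = cfg)

  if (!is.null(cfg$output_dir)) {
    bundle$files <- stage("write_outputs", write_run_outputs(bundle, cfg))
  }
  invisible(bundle)
}

write_run_outputs <- function(bundle, cfg) {
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  files <- write_results_tables(bundle, cfg$output_dir)
  if (isTRUE(cfg$emit_pajek)) {
    pj <- function(net, name) {
      p <- file.path(cfg$output_dir, name)
      write_pajek(net, p)
      p
    }
    files <- c(files,
               pj(bundle$network, "extended_network.net"),
               pj(bundle$decomposition$giant_graph, "giant_component.net"),
               pj(bundle$backbone$graph, "backbone.net"),
               pj(bundle$subnetwork$graph, "seed_subnetwork.net"))
  }
  manifest <- list(
    package = "seednet",
    version = as.character(utils::packageVersion("seednet")),
    config = list(
      seeds = if (is.character(cfg$seeds)) cfg$seeds else "(in-memory)",
      interactions = if (is.character(cfg$interactions)) cfg$interactions
                     else "(in-memory)",
      min_score = cfg$min_score, fraction = cfg$fraction,
      central_gene = if (is.null(cfg$central_gene)) "auto" else cfg$central_gene,
      k_max = cfg$k_max, draws_per_k = cfg$draws_per_k,
      rng_seed = cfg$rng_seed,
      keep_missing_seeds = cfg$keep_missing_seeds,
      emit_pajek = cfg$emit_pajek,
      with_robustness = cfg$with_robustness))
  mp <- file.path(cfg$output_dir, "manifest.yaml")
  yaml::write_yaml(manifest, mp)
  c(files, mp)
}
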