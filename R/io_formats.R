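# Readers/writers: seed lists, STRING-style interaction tables, Pajek .net,
# and the result tables of a full run.

#' Normalize a protein/gene symbol
#'
#' Symbols are treated as opaque identifiers: trimmed, upper-cased, and
#' required to be non-empty tokens without internal whitespace.
#'
#' @param x character vector of raw symbols.
#' @return normalized character vector.
#' @keywords internal
normalize_symbol <- function(x) {
  out <- toupper(trimws(as.character(x)))
  bad <- !nzchar(out) | grepl("[[:space:]]", out)
  if (any(bad)) {
    stop("malformed identifier(s): ",
         paste(sQuote(unique(x[bad])), collapse = ", "), call. = FALSE)
  }
  out
}

#' Read a seed-gene list
#'
#' Accepts either one symbol per line or a TSV with a symbol column plus an
#' optional free-text description. A leading serial-number column and a header
#' row are detected and skipped. Symbols are case-normalized; duplicates are
#' collapsed with a warning. Entry order is preserved (the omission protocol
#' indexes into it).
#'
#' @param path path to the seed list file.
#' @return `data.frame` with columns `symbol` and `description`.
#' @examples
#' seeds <- read_seed_list(system.file("extdata", "eh_seed_genes.tsv",
#'                                     package = "seednet"))
#' nrow(seeds)  # 69 essential-hypertension candidate genes
#' @export
read_seed_list <- function(path) {
  if (!file.exists(path)) stop("seed list file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("seed list file is empty: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  first <- tolower(trimws(fields[[1]][1]))
  if (first %in% c("symbol", "sn", "gene", "#")) fields <- fields[-1L]
  if (length(fields) == 0L) stop("seed list contains a header but no entries", call. = FALSE)
  parse_row <- function(f) {
    f <- trimws(f)
    if (length(f) >= 2L && grepl("^[0-9]+$", f[1])) f <- f[-1L]  # serial number column
    c(symbol = f[1], description = if (length(f) >= 2L) f[2] else "")
  }
  parsed <- t(vapply(fields, parse_row, character(2)))
  symbols <- normalize_symbol(parsed[, "symbol"])
  dup <- duplicated(symbols)
  if (any(dup)) {
    warning("duplicate seed symbol(s) collapsed: ",
            paste(unique(symbols[dup]), collapse = ", "), call. = FALSE)
  }
  data.frame(symbol = symbols[!dup],
             description = parsed[!dup, "description"],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Clean an interaction table
#'
#' Applies the canonical cleaning rules: symbols case-normalized, self-rows
#' dropped, duplicate and reversed-duplicate rows collapsed to one undirected
#' edge keeping the maximum score. Cleaning is idempotent.
#'
#' @param tab `data.frame` with columns `id_a`, `id_b`, `score`.
#' @return cleaned `data.frame`, rows sorted by (`id_a`, `id_b`).
#' @export
clean_interactions <- function(tab) {
  stopifnot(all(c("id_a", "id_b", "score") %in% names(tab)))
  if (any(tab$score < 0)) stop("negative interaction scores are not allowed", call. = FALSE)
  a <- normalize_symbol(tab$id_a)
  b <- normalize_symbol(tab$id_b)
  keep <- a != b
  a <- a[keep]; b <- b[keep]
  score <- as.numeric(tab$score)[keep]
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  if (length(lo) == 0L) {
    return(data.frame(id_a = character(), id_b = character(),
                      score = numeric(), stringsAsFactors = FALSE))
  }
  key <- paste(lo, hi, sep = "\r")
  mx <- tapply(score, key, max)
  parts <- strsplit(names(mx), "\r", fixed = TRUE)
  out <- data.frame(id_a = vapply(parts, `[`, "", 1L),
                    id_b = vapply(parts, `[`, "", 2L),
                    score = as.numeric(mx),
                    stringsAsFactors = FALSE)
  out <- out[order(out$id_a, out$id_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a STRING-style interaction table
#'
#' Parses a delimited text file of pairwise interactions with a confidence
#' score (STRING export style: two identifiers plus a combined score).
#' A two-column dialect without scores is accepted; its rows receive the scale
#' maximum. Scores on a 0-1 scale are rescaled to the canonical 0-1000 scale
#' (`scale = "auto"` rescales when no score exceeds 1). The table is cleaned
#' with [clean_interactions()].
#'
#' @param path path to the interaction file.
#' @param score_column column index (or name, when the file has a header row)
#'   holding the confidence score.
#' @param scale one of `"auto"`, `"s1000"` (scores already 0-1000) or
#'   `"s1"` (scores 0-1, rescaled).
#' @return cleaned `data.frame` with columns `id_a`, `id_b`, `score`
#'   (canonical 0-1000 scale).
#' @export
read_interactions <- function(path, score_column = 3L,
                              scale = c("auto", "s1000", "s1")) {
  scale <- match.arg(scale)
  if (!file.exists(path)) stop("interaction file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !grepl("^#", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stop("interaction file is empty: ", path, call. = FALSE)
  fields <- strsplit(trimws(lines), "[\t ]+")

  header <- NULL
  two_col <- all(lengths(fields) == 2L)
  if (!two_col) {
    probe <- fields[[1]]
    sc <- if (is.character(score_column)) NA_character_ else probe[score_column]
    if (is.character(score_column) || is.na(suppressWarnings(as.numeric(sc)))) {
      header <- fields[[1]]
      fields <- fields[-1L]
      lineno <- lineno[-1L]
      if (length(fields) == 0L) stop("interaction file has a header but no rows", call. = FALSE)
    }
  }
  if (is.character(score_column)) {
    if (is.null(header) || !(score_column %in% header)) {
      stop("unknown score column: ", score_column, call. = FALSE)
    }
    score_column <- match(score_column, header)
  }

  n <- length(fields)
  id_a <- character(n); id_b <- character(n); score <- numeric(n)
  for (i in seq_len(n)) {
    f <- fields[[i]]
    if (two_col) {
      if (length(f) < 2L) {
        stop("unparseable interaction row at line ", lineno[i], call. = FALSE)
      }
      id_a[i] <- f[1]; id_b[i] <- f[2]; score[i] <- NA_real_
    } else {
      if (length(f) < max(3L, score_column)) {
        stop("unparseable interaction row at line ", lineno[i],
             ": expected at least ", max(3L, score_column), " fields", call. = FALSE)
      }
      s <- suppressWarnings(as.numeric(f[score_column]))
      if (is.na(s)) {
        stop("unparseable score at line ", lineno[i], ": ", sQuote(f[score_column]),
             call. = FALSE)
      }
      id_a[i] <- f[1]; id_b[i] <- f[2]; score[i] <- s
    }
  }
  if (two_col) {
    score[] <- 1000
  } else if (scale == "s1" || (scale == "auto" && max(score) <= 1)) {
    score <- score * 1000
  }
  clean_interactions(data.frame(id_a = id_a, id_b = id_b, score = score,
                                stringsAsFactors = FALSE))
}

#' Write an interaction table
#'
#' Writes the canonical three-column TSV dialect read by [read_interactions()].
#'
#' @param tab interaction `data.frame` (`id_a`, `id_b`, `score`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_interactions <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a seed list
#'
#' @param seeds seed `data.frame` (`symbol`, optional `description`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_seed_list <- function(seeds, path) {
  if (is.character(seeds)) seeds <- data.frame(symbol = seeds, description = "")
  if (!"description" %in% names(seeds)) seeds$description <- ""
  utils::write.table(seeds[, c("symbol", "description")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a network in Pajek .net format
#'
#' Vertices are written as 1-based ids with quoted labels under a
#' `*Vertices N` header, followed by an undirected `*Edges` section of id
#' pairs. Isolated vertices are listed with no incident edge line.
#'
#' @param net an `igraph` network with vertex names.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pajek <- function(net, path) {
  if (igraph::vcount(net) == 0L) stop("cannot write an empty network", call. = FALSE)
  labels <- igraph::V(net)$name
  lines <- c(sprintf("*Vertices %d", igraph::vcount(net)),
             sprintf("%d \"%s\"", seq_along(labels), labels),
             "*Edges")
  el <- igraph::as_edgelist(net, names = FALSE)
  if (nrow(el) > 0L) lines <- c(lines, sprintf("%d %d", el[, 1], el[, 2]))
  writeLines(lines, path)
  invisible(path)
}

#' Read a network from Pajek .net format
#'
#' Reads the undirected dialect written by [write_pajek()]; a `*Arcs` section
#' with content is rejected (the networks handled here are undirected).
#' `read_pajek(write_pajek(g))` is the identity on (nodes, edges).
#'
#' @param path path to a `.net` file.
#' @return an `igraph` network; all `seed` flags are `FALSE`.
#' @export
read_pajek <- function(path) {
  if (!file.exists(path)) stop("Pajek file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) stop("empty Pajek file: ", path, call. = FALSE)

  hdr <- grep("^\\*", trimws(lines))
  if (length(hdr) == 0L || !grepl("^\\*vertices", trimws(lines[hdr[1]]), ignore.case = TRUE)) {
    stop("malformed Pajek file: expected '*Vertices N' header at line ",
         if (length(hdr)) hdr[1] else nonblank[1], call. = FALSE)
  }
  nv <- suppressWarnings(as.integer(sub("^\\*\\S+\\s+", "", trimws(lines[hdr[1]]))))
  if (is.na(nv)) stop("malformed '*Vertices' header at line ", hdr[1], call. = FALSE)

  section <- "vertices"
  labels <- character(nv)
  edges <- list()
  for (i in seq_along(lines)) {
    if (i <= hdr[1]) next
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    if (grepl("^\\*", ln)) {
      kw <- tolower(sub("\\s.*$", "", ln))
      if (kw == "*edges") { section <- "edges"; next }
      if (kw == "*arcs") { section <- "arcs"; next }
      stop("unsupported Pajek section ", sQuote(ln), " at line ", i, call. = FALSE)
    }
    if (section == "vertices") {
      m <- regmatches(ln, regexec("^(\\d+)\\s+\"([^\"]*)\"", ln))[[1]]
      if (length(m) == 0L) {
        m <- regmatches(ln, regexec("^(\\d+)\\s+(\\S+)", ln))[[1]]
      }
      if (length(m) == 0L) stop("malformed vertex line ", i, ": ", sQuote(ln), call. = FALSE)
      id <- as.integer(m[2])
      if (id < 1L || id > nv) stop("vertex id out of range at line ", i, call. = FALSE)
      labels[id] <- m[3]
    } else if (section == "edges") {
      f <- strsplit(ln, "\\s+")[[1]]
      if (length(f) < 2L) stop("malformed edge line ", i, ": ", sQuote(ln), call. = FALSE)
      ab <- suppressWarnings(as.integer(f[1:2]))
      if (any(is.na(ab)) || any(ab < 1L) || any(ab > nv)) {
        stop("malformed edge line ", i, ": ", sQuote(ln), call. = FALSE)
      }
      edges[[length(edges) + 1L]] <- ab
    } else if (section == "arcs") {
      stop("'*Arcs' section at line ", i,
           ": directed networks are not supported; use '*Edges'", call. = FALSE)
    }
  }
  if (any(!nzchar(labels))) labels[!nzchar(labels)] <- paste0("V", which(!nzchar(labels)))
  g <- igraph::make_empty_graph(n = nv, directed = FALSE)
  igraph::V(g)$name <- labels
  if (length(edges) > 0L) {
    em <- do.call(rbind, edges)
    g <- igraph::add_edges(g, t(em))
  }
  g <- igraph::simplify(g)
  igraph::V(g)$seed <- FALSE
  g
}

# Format a data.frame for report output: numeric columns at 5 decimals,
# integers left as-is.
format_report <- function(df) {
  for (nm in names(df)) {
    x <- df[[nm]]
    if (is.numeric(x) && !all(x == round(x) | is.na(x))) {
      df[[nm]] <- sprintf("%.5f", x)
    }
  }
  df
}

write_report_tsv <- function(df, path) {
  utils::write.table(format_report(df), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write the result tables of a full analysis
#'
#' Emits one delimited file per report: global network statistics, the
#' per-node centrality table, backbone membership, the key-node
#' classification, the seed-subnetwork betweenness ranking, and (when
#' robustness was run) the per-group and summary robustness tables plus the
#' per-test-network detail. Floats are written at 5 decimals.
#'
#' @param bundle a result bundle from [run_full_analysis()], or any list with
#'   a subset of its elements (`stats`, `centralities`, `backbone`,
#'   `key_nodes`, `subnetwork`, `robustness`, `robustness_summary`).
#' @param dir output directory (created if missing).
#' @return character vector of the files written, invisibly.
#' @export
write_results_tables <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  put <- function(df, name) {
    p <- file.path(dir, name)
    write_report_tsv(df, p)
    written <<- c(written, p)
  }
  if (!is.null(bundle$stats)) {
    s <- bundle$stats
    put(data.frame(N = s$n_nodes, E = s$n_edges,
                   avg_degree = s$avg_degree, diameter = s$diameter,
                   mspl = s$mspl), "network_stats.tsv")
  }
  if (!is.null(bundle$centralities)) put(bundle$centralities, "centrality.tsv")
  if (!is.null(bundle$backbone)) put(bundle$backbone$members, "backbone.tsv")
  if (!is.null(bundle$key_nodes)) put(bundle$key_nodes$table, "key_nodes.tsv")
  if (!is.null(bundle$subnetwork)) put(bundle$subnetwork$bc_ranking, "subnetwork_bc.tsv")
  if (!is.null(bundle$robustness)) put(bundle$robustness$detail, "robustness_detail.tsv")
  if (!is.null(bundle$robustness_summary)) {
    rs <- bundle$robustness_summary
    put(rs$per_k, "robustness_per_k.tsv")
    summary_row <- data.frame(k = "Summary", t(rs$frequency_totals),
                              accuracy = rs$overall_accuracy,
                              n_networks = rs$n_total, check.names = FALSE)
    per_k_chr <- rs$per_k
    per_k_chr$k <- as.character(per_k_chr$k)
    put(rbind(per_k_chr, summary_row), "robustness_summary.tsv")
  }
  invisible(written)
}
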