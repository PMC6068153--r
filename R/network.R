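# Gene-network handling: multi-study edge lists, the consensus network
# (nodes/edges supported by at least `min_support` studies), and graph
# neighborhoods used by key-driver analysis.

#' Construct a gene network from an edge data frame
#'
#' @param edges Data frame with columns `source`, `target` and optionally
#'   `support` (defaults to 1). Self-loops are dropped with a warning.
#' @param nodes Optional character vector of nodes (to keep isolated
#'   nodes); defaults to the union of edge endpoints.
#' @param directed Logical; if FALSE (default) edges are undirected and
#'   stored with lexicographically ordered endpoints.
#' @return Object of class `gene_network`.
#' @export
gene_network <- function(edges, nodes = NULL, directed = FALSE) {
  stopifnot(is.data.frame(edges))
  if (!all(c("source", "target") %in% names(edges))) {
    stopf("edges need `source` and `target` columns")
  }
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  if (is.null(edges$support)) edges$support <- 1L
  loops <- edges$source == edges$target
  if (any(loops)) {
    warnf("dropping %d self-loop(s)", sum(loops))
    edges <- edges[!loops, , drop = FALSE]
  }
  if (!directed && nrow(edges) > 0) {
    a <- pmin(edges$source, edges$target)
    b <- pmax(edges$source, edges$target)
    edges$source <- a; edges$target <- b
  }
  key <- paste(edges$source, edges$target, sep = "\r")
  if (anyDuplicated(key)) {
    edges <- edges[!duplicated(key), , drop = FALSE]
  }
  endpoint_nodes <- unique(c(edges$source, edges$target))
  nodes <- sort(unique(c(nodes, endpoint_nodes)))
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, directed = isTRUE(directed)),
            class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("gene_network: %d nodes, %d %s edges\n",
              length(x$nodes), nrow(x$edges),
              if (x$directed) "directed" else "undirected"))
  invisible(x)
}

#' Read multi-study edge lists from three-column TSV files
#'
#' Each row is `source<TAB>target<TAB>study`; a header row naming those
#' columns is accepted. One `gene_network` is returned per study label.
#'
#' @param paths Character vector of file paths.
#' @param directed Logical, passed to [gene_network()].
#' @return Named list of `gene_network` objects, one per study.
#' @export
read_edge_lists <- function(paths, directed = FALSE) {
  rows <- list()
  for (path in paths) {
    if (!file.exists(path)) stopf("file not found: %s", path)
    lines <- readLines(path)
    if (length(lines) == 0) next
    start <- 1L
    first <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
    if (identical(tolower(first[1:min(2, length(first))]), c("source", "target"))) {
      start <- 2L
    }
    for (ln in seq(start, length.out = max(0, length(lines) - start + 1L))) {
      if (!nzchar(lines[ln])) next
      fields <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
      if (length(fields) != 3) {
        stopf("malformed edge row in '%s' at line %d: expected 3 tab-separated columns, got %d",
              path, ln, length(fields))
      }
      rows[[length(rows) + 1L]] <- fields
    }
  }
  if (length(rows) == 0) stopf("no edges found in the given file(s)")
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(df) <- c("source", "target", "study")
  studies <- unique(df$study)
  nets <- lapply(studies, function(st) {
    gene_network(df[df$study == st, c("source", "target"), drop = FALSE],
                 directed = directed)
  })
  names(nets) <- studies
  nets
}

#' Write per-study networks as a single three-column edge-list TSV
#' @param networks Named list of `gene_network`s (names = study labels).
#' @param path Output path.
#' @export
write_edge_lists <- function(networks, path) {
  dfs <- lapply(names(networks), function(st) {
    e <- networks[[st]]$edges
    data.frame(source = e$source, target = e$target, study = st,
               stringsAsFactors = FALSE)
  })
  write_tsv(do.call(rbind, dfs), path)
}

#' Consensus network across studies
#'
#' Keeps exactly the edges present in at least `min_support` study
#' networks and the nodes present in at least `min_support` study
#' networks; kept edges are further restricted to kept endpoints. Edge
#' identity ignores direction when the networks are undirected.
#'
#' @param networks List of >= 2 `gene_network` objects.
#' @param min_support Minimum number of supporting studies (default 2).
#' @return A `gene_network` whose edges carry their study-support count.
#' @export
consensus_network <- function(networks, min_support = 2L) {
  if (length(networks) < 2) stopf("consensus needs >= 2 study networks")
  stopifnot(all(vapply(networks, inherits, logical(1), "gene_network")))
  assert_scalar_number(min_support, "min_support", lower = 1)
  directed <- networks[[1]]$directed
  edge_keys <- lapply(networks, function(nw) {
    unique(paste(nw$edges$source, nw$edges$target, sep = "\r"))
  })
  edge_support <- table(unlist(edge_keys))
  node_support <- table(unlist(lapply(networks, `[[`, "nodes")))
  kept_nodes <- names(node_support)[node_support >= min_support]
  kept_keys <- names(edge_support)[edge_support >= min_support]
  if (length(kept_keys) > 0) {
    parts <- do.call(rbind, strsplit(kept_keys, "\r", fixed = TRUE))
    keep <- parts[, 1] %in% kept_nodes & parts[, 2] %in% kept_nodes
    edges <- data.frame(source = parts[keep, 1], target = parts[keep, 2],
                        support = as.integer(edge_support[kept_keys])[keep],
                        stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(source = character(), target = character(),
                        support = integer(), stringsAsFactors = FALSE)
  }
  gene_network(edges, nodes = kept_nodes, directed = directed)
}

.as_igraph <- function(network) {
  igraph::graph_from_data_frame(
    network$edges[, c("source", "target"), drop = FALSE],
    directed = network$directed, vertices = network$nodes)
}

#' Graph neighborhood of a gene
#'
#' Nodes reachable within `hops` steps of `gene`, excluding the gene
#' itself. Steps are undirected unless `mode = "out"`.
#'
#' @param network A `gene_network`.
#' @param gene Node identifier.
#' @param hops Maximum path length (default 1).
#' @param mode "all" (undirected, default) or "out" (downstream only).
#' @return Character vector of neighbor nodes.
#' @export
neighborhood <- function(network, gene, hops = 1L, mode = c("all", "out")) {
  stopifnot(inherits(network, "gene_network"))
  mode <- match.arg(mode)
  if (!gene %in% network$nodes) stopf("gene '%s' is not in the network", gene)
  assert_scalar_number(hops, "hops", lower = 1)
  g <- .as_igraph(network)
  nb <- igraph::ego(g, order = hops, nodes = gene, mode = mode, mindist = 1)[[1]]
  sort(names(nb))
}
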