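# Weighted gene regulatory network: construction, merging, summaries.
#
# Graphs are plain undirected igraph objects. Node weights (literature
# evidence counts) live in the vertex attribute "evidence"; membership
# classes from the disease-target merge live in "membership".

.header_names <- c("gene_a", "gene_b", "from", "to", "source", "target",
                   "node1", "node2", "gene1", "gene2", "protein_a", "protein_b")

#' Load an undirected gene interaction network from a TSV edge list
#'
#' Reads a two-column (or wider; extra columns ignored) tab-separated edge
#' list of gene symbols and returns a simple undirected graph: self-loops are
#' dropped and duplicate edges (in either orientation) are collapsed. A
#' header row is detected when both fields of the first line match common
#' column names such as `gene_a`/`gene_b` or `from`/`to`.
#'
#' @param path Path to a TSV file, one interaction per row.
#' @return An undirected simple [igraph::igraph] with graph attributes
#'   `n_selfloops_dropped` and `n_duplicates_dropped` recording the rows
#'   removed by simplification.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("A\tB", "B\tA", "A\tA", "B\tC"), tf)
#' g <- load_edge_list(tf)
#' igraph::ecount(g)  # 2
#' @export
load_edge_list <- function(path) {
  if (!file.exists(path)) {
    stop("edge list file not found: ", path)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    stop("edge list is empty: ", path)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  first <- tolower(trimws(fields[[1L]]))
  start <- if (length(first) >= 2L && all(first[1:2] %in% .header_names)) 2L else 1L
  if (start > length(lines)) {
    stop("edge list contains a header but no data rows: ", path)
  }
  rows <- vector("list", length(lines) - start + 1L)
  for (i in seq(start, length(lines))) {
    f <- trimws(fields[[i]])
    if (length(f) < 2L || !nzchar(f[1L]) || !nzchar(f[2L])) {
      stop("malformed edge row at line ", i, " of ", path, ": ", lines[i])
    }
    rows[[i - start + 1L]] <- f[1:2]
  }
  em <- do.call(rbind, rows)
  edge_list_to_network(em[, 1L], em[, 2L])
}

#' Build a simple undirected network from paired gene vectors
#'
#' @param from,to Character vectors of equal length naming edge endpoints.
#' @return An undirected simple igraph; see [load_edge_list()].
#' @export
edge_list_to_network <- function(from, to) {
  stopifnot(length(from) == length(to))
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(from), to = as.character(to),
               stringsAsFactors = FALSE),
    directed = FALSE)
  n_loops <- sum(igraph::which_loop(g))
  g <- igraph::simplify(g, remove.multiple = FALSE, remove.loops = TRUE)
  g2 <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  n_dup <- igraph::ecount(g) - igraph::ecount(g2)
  g2 <- igraph::set_graph_attr(g2, "n_selfloops_dropped", n_loops)
  g2 <- igraph::set_graph_attr(g2, "n_duplicates_dropped", n_dup)
  g2
}

#' Attach literature-evidence weights to network nodes
#'
#' Maps a pathogenetic-gene table (DisGeNET-style: gene symbol plus the
#' number of supporting publications) onto the network. Genes present in the
#' table become weighted nodes; network nodes absent from the table get
#' weight 0. Genes in the table that are missing from the network are
#' reported via the `unmapped_genes` graph attribute, never added as nodes.
#'
#' @param net An igraph network from [load_edge_list()].
#' @param genes A data.frame with columns `gene_id` and `evidence_count`.
#' @return `net` with a numeric vertex attribute `evidence` and a graph
#'   attribute `unmapped_genes` (character vector).
#' @export
attach_weights <- function(net, genes) {
  stopifnot(is.data.frame(genes),
            all(c("gene_id", "evidence_count") %in% names(genes)))
  gid <- as.character(genes$gene_id)
  cnt <- genes$evidence_count
  if (any(!nzchar(gid))) stop("empty gene_id in evidence table")
  if (any(is.na(cnt)) || any(cnt < 0)) stop("evidence_count must be >= 0")
  if (anyDuplicated(gid)) {
    agg <- tapply(cnt, gid, function(x) length(unique(x)))
    bad <- names(agg)[agg > 1L]
    if (length(bad)) {
      stop("conflicting evidence counts for gene(s): ",
           paste(bad, collapse = ", "))
    }
    keep <- !duplicated(gid)
    gid <- gid[keep]; cnt <- cnt[keep]
  }
  nodes <- igraph::V(net)$name
  w <- cnt[match(nodes, gid)]
  w[is.na(w)] <- 0
  net <- igraph::set_vertex_attr(net, "evidence", value = w)
  igraph::set_graph_attr(net, "unmapped_genes", setdiff(gid, nodes))
}

#' Merge the disease gene set and the component-target set into one network
#'
#' Induces the subgraph of the PPI on the union of pathogenetic genes and
#' component targets, annotating each retained node as `"disease"` (only),
#' `"target"` (only) or `"both"` (the essential common targets). This is the
#' disease-target network on which effective proteins are selected.
#'
#' @param ppi Weighted PPI network (igraph).
#' @param disease_genes,targets Character vectors of gene ids.
#' @return Induced subgraph with a `membership` vertex attribute.
#' @export
merge_disease_target_network <- function(ppi, disease_genes, targets) {
  disease_genes <- unique(as.character(disease_genes))
  targets <- unique(as.character(targets))
  keep <- intersect(union(disease_genes, targets), igraph::V(ppi)$name)
  if (length(keep) == 0L) {
    stop("no disease gene or target maps onto the PPI network")
  }
  sub <- igraph::induced_subgraph(ppi, keep)
  nm <- igraph::V(sub)$name
  cls <- ifelse(nm %in% disease_genes & nm %in% targets, "both",
                ifelse(nm %in% disease_genes, "disease", "target"))
  igraph::set_vertex_attr(sub, "membership", value = cls)
}

#' Summarize a gene network
#'
#' Reports node and edge counts, the edge-to-node ratio E/N and the mean
#' degree 2E/N. Published "average degree" figures for dense PPI networks
#' are sometimes the E/N ratio rather than the conventional mean degree;
#' both are returned (with 2-decimal rounded copies) so either convention
#' can be reproduced.
#'
#' @param net An igraph network.
#' @return A list of class `network_summary`: `n_nodes`, `n_edges`,
#'   `edge_node_ratio`, `mean_degree`, their `_rounded` copies, and a
#'   per-node `degree` table.
#' @export
summarize_network <- function(net) {
  n <- igraph::vcount(net)
  if (n == 0L) stop("cannot summarize an empty network")
  e <- igraph::ecount(net)
  deg <- igraph::degree(net)
  out <- list(
    n_nodes = n,
    n_edges = e,
    edge_node_ratio = e / n,
    mean_degree = 2 * e / n,
    edge_node_ratio_rounded = round(e / n, 2),
    mean_degree_rounded = round(2 * e / n, 2),
    degree = data.frame(node = names(deg), degree = as.integer(deg),
                        row.names = NULL, stringsAsFactors = FALSE)
  )
  class(out) <- "network_summary"
  out
}

#' @export
print.network_summary <- function(x, ...) {
  cat("Gene network summary\n")
  cat(sprintf("  nodes: %d   edges: %d\n", x$n_nodes, x$n_edges))
  cat(sprintf("  edges/nodes: %.2f   mean degree (2E/N): %.2f\n",
              x$edge_node_ratio, x$mean_degree))
  invisible(x)
}

#' Write a network summary as JSON
#'
#' @param summary A `network_summary` from [summarize_network()].
#' @param path Output file.
#' @export
write_network_summary <- function(summary, path) {
  jsonlite::write_json(
    list(n_nodes = summary$n_nodes, n_edges = summary$n_edges,
         edge_node_ratio = summary$edge_node_ratio,
         mean_degree = summary$mean_degree),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write an edge list TSV
#'
#' @param net An igraph network.
#' @param path Output file; columns `gene_a`, `gene_b`.
#' @export
write_edge_list <- function(net, path) {
  el <- igraph::as_edgelist(net)
  utils::write.table(data.frame(gene_a = el[, 1], gene_b = el[, 2]),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene evidence table TSV
#'
#' @param path TSV with columns `gene_id` and `evidence_count`.
#' @return data.frame with those two columns.
#' @export
read_gene_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "evidence_count") %in% names(df))) {
    names(df)[1:2] <- c("gene_id", "evidence_count")
  }
  df$gene_id <- as.character(df$gene_id)
  df$evidence_count <- as.integer(df$evidence_count)
  df[, c("gene_id", "evidence_count")]
}
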