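# Potential effect score (PES) on the tripartite component-target-pathway
# (C-T-P) network.
#
# For component k:
#
#   PES(k) = [ sum of degrees of k's direct neighbours ] x
#            [ |reachable(k)| / |V|  x
#              sum over reachable pathways p of
#                (Delta_k + 1 - dist(k, p)) / Delta_k ]^2
#
# where Delta_k = max over reachable pathways of dist(k, p), distances are
# unweighted hop counts on the undirected tripartite graph, and unreachable
# pathways contribute nothing (distance treated as infinite on disconnected
# parts). Scores are min-max normalized to [0, 1].

#' Assemble the component-target-pathway network
#'
#' Components connect to their targets (bipartite map) and targets connect
#' to the pathways that contain them (gene-set membership). Pathway genes
#' that are not targets of any component are not added; pathways left with
#' no member target are dropped (recorded in the `dropped_pathways` graph
#' attribute). Node classes are kept in the vertex attribute `type`
#' (`"component"`, `"target"`, `"pathway"`).
#'
#' @param ctmap Named list component id -> target genes (see [ct_map()]).
#' @param pathways A gene-set collection from [gene_set_collection()] or a
#'   plain named list of gene vectors.
#' @return An undirected igraph with a `type` vertex attribute.
#' @export
build_ctp <- function(ctmap, pathways) {
  if (inherits(pathways, "gene_set_collection")) pathways <- pathways$sets
  comp <- names(ctmap)
  targ <- unique(unlist(ctmap, use.names = FALSE))
  path_ids <- names(pathways)
  clash <- c(intersect(comp, targ), intersect(comp, path_ids),
             intersect(targ, path_ids))
  if (length(clash)) {
    stop("identifier collision across node classes (namespace components, ",
         "targets and pathways): ", paste(unique(clash), collapse = ", "))
  }
  ct_edges <- do.call(rbind, lapply(comp, function(k) {
    t <- unique(ctmap[[k]])
    if (length(t)) cbind(k, t) else NULL
  }))
  tp <- lapply(pathways, function(g) intersect(unique(g), targ))
  dropped <- path_ids[lengths(tp) == 0L]
  tp <- tp[lengths(tp) > 0L]
  tp_edges <- do.call(rbind, lapply(names(tp), function(p) cbind(tp[[p]], p)))
  edges <- rbind(ct_edges, tp_edges)
  if (is.null(edges)) stop("C-T-P network has no edges")
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges[, 1], to = edges[, 2],
               stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(
      name = c(comp, targ, names(tp)),
      type = rep(c("component", "target", "pathway"),
                 c(length(comp), length(targ), length(tp))),
      stringsAsFactors = FALSE))
  g <- igraph::simplify(g)
  igraph::set_graph_attr(g, "dropped_pathways", dropped)
}

#' Potential effect score of one component
#'
#' @param ctp C-T-P network from [build_ctp()].
#' @param component Component node name.
#' @return One-row data.frame with `component_id`, `degree_mass` (sum of
#'   neighbours' degrees), `reach_fraction` (reachable nodes excluding the
#'   component itself, over |V|), `proximity_sum`, `raw_pes`.
#' @export
compute_pes <- function(ctp, component) {
  types <- igraph::V(ctp)$type
  if (!(component %in% igraph::V(ctp)$name[types == "component"])) {
    stop("component not in C-T-P network: ", component)
  }
  nb <- igraph::neighbors(ctp, component)
  degree_mass <- if (length(nb)) sum(igraph::degree(ctp)[nb]) else 0
  d <- igraph::distances(ctp, v = component)[1L, ]
  reach <- is.finite(d) & d > 0
  n_reach <- sum(reach)
  pw <- reach & types == "pathway"
  if (degree_mass == 0 || !any(pw)) {
    prox <- 0
    reach_frac <- n_reach / igraph::vcount(ctp)
    raw <- 0
  } else {
    delta <- max(d[pw])
    prox <- sum((delta + 1 - d[pw]) / delta)
    reach_frac <- n_reach / igraph::vcount(ctp)
    raw <- degree_mass * (reach_frac * prox)^2
  }
  data.frame(component_id = component, degree_mass = degree_mass,
             reach_fraction = reach_frac, proximity_sum = prox,
             raw_pes = raw, stringsAsFactors = FALSE)
}

#' Score every component in the C-T-P network
#'
#' @param ctp C-T-P network from [build_ctp()].
#' @return data.frame of [compute_pes()] rows, one per component.
#' @export
compute_all_pes <- function(ctp) {
  comps <- igraph::V(ctp)$name[igraph::V(ctp)$type == "component"]
  out <- do.call(rbind, lapply(comps, compute_pes, ctp = ctp))
  rownames(out) <- NULL
  out
}

#' Min-max normalize potential effect scores to [0, 1]
#'
#' `(x - min) / (max - min)`; when all raw scores are equal every score maps
#' to 0 (the degenerate case never arises on realistic data). Output is
#' sorted descending by normalized score, ties by component id.
#'
#' @param scores data.frame from [compute_all_pes()] (needs `component_id`
#'   and `raw_pes`).
#' @return The input with a `normalized_pes` column, sorted descending.
#' @export
normalize_pes <- function(scores) {
  stopifnot(is.data.frame(scores), nrow(scores) >= 1L,
            all(c("component_id", "raw_pes") %in% names(scores)))
  rng <- range(scores$raw_pes)
  scores$normalized_pes <- if (rng[1] == rng[2]) {
    rep(0, nrow(scores))
  } else {
    (scores$raw_pes - rng[1]) / (rng[2] - rng[1])
  }
  scores <- scores[order(-scores$normalized_pes, scores$component_id), ,
                   drop = FALSE]
  rownames(scores) <- NULL
  scores
}

#' Write the PES table as TSV
#'
#' @param scores Normalized table from [normalize_pes()].
#' @param path Output file.
#' @export
write_pes <- function(scores, path) {
  utils::write.table(
    scores[, c("component_id", "raw_pes", "normalized_pes")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
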