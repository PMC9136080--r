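# Node-importance scoring and functional response space (FRS) extraction.
#
# The importance of node s is
#
#   Nim(s) = [ sum_{v != s != t} sigma_vt(s) / sigma_vt ] x
#            [ sum_{x != s} 1 / d(s, x)^2 ]
#
# i.e. raw shortest-path betweenness (unordered pairs, endpoints excluded)
# times an inverse-squared-distance proximity term. Disconnected pairs
# contribute nothing to either factor (1/d treated as 0 at infinite
# distance). Effective proteins are the upper half of the ascending Nim
# ranking; they induce the functional response space.

.baseline_methods <- c("degree", "closeness", "clustering_coefficient")

#' Node importance score of a single node
#'
#' @param net An undirected igraph network.
#' @param node A node name present in `net`.
#' @param proximity One of `"inverse_square"` (default; sum of 1/d(s,x)^2)
#'   or `"square_of_sum"` (the alternative reading (sum of 1/d)^2).
#' @return A one-row data.frame with columns `node`, `betweenness_term`,
#'   `proximity_term` and `nim`.
#' @examples
#' g <- igraph::make_graph(~ A - B - C)
#' node_importance(g, "B")  # betweenness 1, proximity 2, nim 2
#' @export
node_importance <- function(net, node,
                            proximity = c("inverse_square", "square_of_sum")) {
  proximity <- match.arg(proximity)
  if (!(node %in% igraph::V(net)$name)) {
    stop("node not in network: ", node)
  }
  tab <- score_all(net, proximity = proximity)
  tab[tab$node == node, , drop = FALSE]
}

#' Score every node and rank ascending by importance
#'
#' Betweenness uses exact shortest-path counts over unordered pairs with
#' endpoints excluded and no normalization; the proximity factor sums
#' 1/d(s,x)^2 over all other nodes, with unreachable nodes contributing 0.
#' The returned table is sorted ascending by `nim` (ties broken by node id),
#' mirroring the construction of the ranking variable Q.
#'
#' @inheritParams node_importance
#' @return A data.frame with columns `node`, `betweenness_term`,
#'   `proximity_term`, `nim` and `rank` (1 = smallest), sorted ascending.
#' @export
score_all <- function(net, proximity = c("inverse_square", "square_of_sum")) {
  proximity <- match.arg(proximity)
  if (igraph::vcount(net) == 0L) stop("empty network")
  btw <- igraph::betweenness(net, directed = FALSE, normalized = FALSE)
  d <- igraph::distances(net)
  inv <- 1 / d
  inv[!is.finite(d) | d == 0] <- 0
  prox <- if (proximity == "inverse_square") {
    rowSums(inv^2)
  } else {
    rowSums(inv)^2
  }
  tab <- data.frame(node = igraph::V(net)$name,
                    betweenness_term = as.numeric(btw),
                    proximity_term = as.numeric(prox),
                    stringsAsFactors = FALSE)
  tab$nim <- tab$betweenness_term * tab$proximity_term
  tab <- tab[order(tab$nim, tab$node), , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  tab
}

#' Generic centrality ranking for the baseline selectors
#'
#' @param net An undirected igraph network.
#' @param method `"degree"`, `"closeness"` or `"clustering_coefficient"`.
#' @return Ascending ranked data.frame with columns `node`, `score`, `rank`.
#' @export
score_baseline <- function(net, method) {
  if (!method %in% .baseline_methods) {
    stop("unknown method '", method, "'; valid methods: ",
         paste(.baseline_methods, collapse = ", "))
  }
  score <- switch(method,
    degree = igraph::degree(net),
    closeness = {
      s <- suppressWarnings(igraph::closeness(net, mode = "all"))
      s[is.na(s)] <- 0
      s
    },
    clustering_coefficient =
      igraph::transitivity(net, type = "local", isolates = "zero")
  )
  tab <- data.frame(node = igraph::V(net)$name, score = as.numeric(score),
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$score, tab$node), , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  tab
}

.frs_from_ranked <- function(ranked, value_col, rule) {
  n <- nrow(ranked)
  vals <- ranked[[value_col]]
  if (rule == "median") {
    k <- if (n %% 2L == 1L) (n + 1L) %/% 2L else n %/% 2L
    cut_value <- if (n %% 2L == 1L) {
      vals[(n + 1L) %/% 2L]
    } else {
      (vals[n %/% 2L] + vals[n %/% 2L + 1L]) / 2
    }
    sel <- ranked$node[seq(n - k + 1L, n)]
    tie_at_cut <- n > 1L && vals[n - k + 1L] == vals[max(1L, n - k)]
  } else {  # mean threshold: keep nodes scoring above the average
    cut_value <- mean(vals)
    sel <- ranked$node[vals > cut_value]
    k <- length(sel)
    tie_at_cut <- FALSE
  }
  out <- list(selected = sel, rejected = setdiff(ranked$node, sel),
              cut_value = cut_value, n_selected = k, rule = rule,
              tie_at_cut = tie_at_cut)
  class(out) <- "frs"
  out
}

#' Select the functional response space (effective proteins)
#'
#' Takes the ascending importance ranking and keeps its upper half: the top
#' (|V|+1)/2 nodes when |V| is odd and the top |V|/2 when even (the
#' `"median"` rule, the default). The reported cut value is the median score
#' (the middle score for odd |V|, the midpoint of the two middle scores for
#' even |V|). A `"mean"` rule keeping nodes scoring strictly above the
#' average is available for comparison.
#'
#' @param ranked Ascending ranking from [score_all()] or [score_baseline()].
#' @param rule `"median"` (upper half, default) or `"mean"`.
#' @return A list of class `frs` with elements `selected`, `rejected`,
#'   `cut_value`, `n_selected`, `rule`, `tie_at_cut`.
#' @export
select_frs <- function(ranked, rule = c("median", "mean")) {
  rule <- match.arg(rule)
  stopifnot(is.data.frame(ranked), nrow(ranked) >= 1L)
  col <- if ("nim" %in% names(ranked)) "nim" else "score"
  .frs_from_ranked(ranked, col, rule)
}

#' Baseline FRS selection with a conventional centrality
#'
#' Applies the same upper-half selection rule to a degree, closeness or
#' local clustering-coefficient ranking, for benchmarking the importance
#' measure against traditional centralities.
#'
#' @inheritParams score_baseline
#' @inheritParams select_frs
#' @return An `frs` list; see [select_frs()].
#' @export
baseline_select <- function(net, method, rule = c("median", "mean")) {
  rule <- match.arg(rule)
  select_frs(score_baseline(net, method), rule = rule)
}

#' @export
print.frs <- function(x, ...) {
  cat(sprintf("FRS: %d effective proteins (%s rule, cut value %.4g)\n",
              x$n_selected, x$rule, x$cut_value))
  invisible(x)
}

#' Write an importance/selection table as TSV
#'
#' @param ranked Table from [score_all()].
#' @param frs An `frs` object from [select_frs()].
#' @param path Output file.
#' @export
write_frs_table <- function(ranked, frs, path) {
  ranked$selected <- ranked$node %in% frs$selected
  utils::write.table(ranked, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
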