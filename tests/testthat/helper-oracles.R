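# Brute-force oracles, independent of the igraph algorithms the package
# uses: plain-R BFS for distances and shortest-path counts, direct
# summation for betweenness and proximity, and exhaustive draw enumeration
# for the hypergeometric tail.

# adjacency list (names -> character vectors) from an igraph object
bf_adj <- function(g) {
  nodes <- igraph::V(g)$name
  el <- igraph::as_edgelist(g)
  adj <- stats::setNames(lapply(nodes, function(x) character(0)), nodes)
  for (i in seq_len(nrow(el))) {
    a <- el[i, 1]; b <- el[i, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

# single-source BFS: distances and number of shortest paths
bf_bfs <- function(adj, src) {
  nodes <- names(adj)
  dist <- stats::setNames(rep(Inf, length(nodes)), nodes)
  sigma <- stats::setNames(rep(0, length(nodes)), nodes)
  dist[src] <- 0; sigma[src] <- 1
  frontier <- src
  while (length(frontier)) {
    nxt <- character(0)
    for (u in frontier) {
      for (v in adj[[u]]) {
        if (is.infinite(dist[v])) {
          dist[v] <- dist[u] + 1
          nxt <- c(nxt, v)
        }
        if (dist[v] == dist[u] + 1) sigma[v] <- sigma[v] + sigma[u]
      }
    }
    frontier <- unique(nxt)
  }
  list(dist = dist, sigma = sigma)
}

bf_all <- function(g) {
  adj <- bf_adj(g)
  lapply(stats::setNames(names(adj), names(adj)),
         function(s) bf_bfs(adj, s))
}

# raw betweenness of s: sum over unordered pairs {v,t}, endpoints excluded
bf_betweenness <- function(g, s, all = bf_all(g)) {
  nodes <- names(all)
  others <- setdiff(nodes, s)
  total <- 0
  for (i in seq_along(others)) {
    for (j in seq_len(i - 1L)) {
      v <- others[i]; t <- others[j]
      dvt <- all[[v]]$dist[t]
      if (!is.finite(dvt)) next
      dvs <- all[[v]]$dist[s]; dst <- all[[s]]$dist[t]
      if (is.finite(dvs) && is.finite(dst) && dvs + dst == dvt) {
        total <- total +
          (all[[v]]$sigma[s] * all[[s]]$sigma[t]) / all[[v]]$sigma[t]
      }
    }
  }
  unname(total)
}

bf_proximity <- function(g, s, all = bf_all(g)) {
  d <- all[[s]]$dist
  d <- d[names(d) != s]
  sum(1 / d[is.finite(d)]^2)
}

bf_nim <- function(g, s, all = bf_all(g)) {
  bf_betweenness(g, s, all) * bf_proximity(g, s, all)
}

# exhaustive hypergeometric upper tail: P[overlap >= k] when drawing q
# genes from a universe containing a set of size m
bf_hyper_tail <- function(universe, set, q, k) {
  draws <- utils::combn(universe, q, simplify = FALSE)
  mean(vapply(draws, function(d) length(intersect(d, set)) >= k, logical(1)))
}

# independent PES recomputation from the edge list of a C-T-P graph
bf_pes <- function(g, component) {
  adj <- bf_adj(g)
  types <- stats::setNames(igraph::V(g)$type, igraph::V(g)$name)
  deg <- lengths(adj)
  degree_mass <- sum(deg[adj[[component]]])
  d <- bf_bfs(adj, component)$dist
  reach <- names(d)[is.finite(d) & d > 0]
  pw <- reach[types[reach] == "pathway"]
  if (degree_mass == 0 || length(pw) == 0) return(0)
  delta <- max(d[pw])
  prox <- sum((delta + 1 - d[pw]) / delta)
  degree_mass * ((length(reach) / length(adj)) * prox)^2
}

# small shipped graphs (<= 12 nodes) used by the oracle-equivalence suites
shipped_graphs <- function() {
  gs <- list(
    path3 = igraph::make_graph(~ A - B - C),
    path5 = igraph::make_ring(5, circular = FALSE),
    star5 = igraph::make_star(5, mode = "undirected"),
    cycle6 = igraph::make_ring(6),
    complete5 = igraph::make_full_graph(5),
    tree7 = igraph::make_tree(7, children = 2, mode = "undirected"),
    two_comp = igraph::disjoint_union(igraph::make_ring(4),
                                      igraph::make_full_graph(3))
  )
  for (nm in names(gs)) {
    if (is.null(igraph::V(gs[[nm]])$name)) {
      gs[[nm]] <- igraph::set_vertex_attr(
        gs[[nm]], "name", value = paste0("n", seq_len(igraph::vcount(gs[[nm]]))))
    }
  }
  set.seed(20240101)
  for (i in 1:6) {
    n <- sample(5:8, 1L)
    repeat {
      g <- igraph::sample_gnp(n, 0.45)
      if (igraph::is_connected(g)) break
    }
    g <- igraph::set_vertex_attr(g, "name", value = paste0("r", seq_len(n)))
    gs[[paste0("rand", i)]] <- g
  }
  gs
}

# write a tiny TSV fixture and return its path
write_tsv_fixture <- function(lines) {
  tf <- tempfile(fileext = ".tsv")
  writeLines(lines, tf)
  tf
}
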