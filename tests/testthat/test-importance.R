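test_that("node importance matches hand-derived values on canonical graphs", {
  p3 <- igraph::make_graph(~ A - B - C)
  b <- node_importance(p3, "B")
  expect_equal(b$betweenness_term, 1)
  expect_equal(b$proximity_term, 2)
  expect_equal(b$nim, 2)
  expect_equal(node_importance(p3, "A")$nim, 0)  # endpoints carry no paths

  star <- igraph::make_star(5, mode = "undirected")
  star <- igraph::set_vertex_attr(star, "name",
                                  value = c("c", "l1", "l2", "l3", "l4"))
  cc <- node_importance(star, "c")
  expect_equal(cc$betweenness_term, 6)
  expect_equal(cc$proximity_term, 4)
  expect_equal(cc$nim, 24)

  expect_error(node_importance(p3, "Z"), "not in network")
})

test_that("importance terms match brute-force enumeration on small graphs", {
  for (nm in names(shipped_graphs())) {
    g <- shipped_graphs()[[nm]]
    all <- bf_all(g)
    tab <- score_all(g)
    for (i in seq_len(nrow(tab))) {
      s <- tab$node[i]
      expect_equal(tab$betweenness_term[i], bf_betweenness(g, s, all),
                   tolerance = 1e-9, label = paste(nm, s, "betweenness"))
      expect_equal(tab$proximity_term[i], bf_proximity(g, s, all),
                   tolerance = 1e-9, label = paste(nm, s, "proximity"))
      expect_equal(tab$nim[i], bf_nim(g, s, all), tolerance = 1e-9,
                   label = paste(nm, s, "nim"))
    }
  }
})

test_that("ranking is ascending, complete and id-stable under ties", {
  g <- igraph::make_ring(6)
  g <- igraph::set_vertex_attr(g, "name", value = paste0("v", 6:1))
  tab <- score_all(g)
  expect_equal(nrow(tab), 6L)
  expect_true(!is.unsorted(tab$nim))
  # all ring nodes tie; order must be lexicographic by id
  expect_identical(tab$node, sort(paste0("v", 1:6)))

  el <- igraph::make_empty_graph(3, directed = FALSE)
  el <- igraph::set_vertex_attr(el, "name", value = c("b", "a", "c"))
  tab0 <- score_all(el)
  expect_true(all(tab0$nim == 0))
  expect_identical(tab0$node, c("a", "b", "c"))
})

test_that("relabeling nodes permutes scores identically", {
  set.seed(5)
  g <- igraph::sample_gnp(9, 0.4)
  g <- igraph::set_vertex_attr(g, "name", value = paste0("x", 1:9))
  perm <- sample(paste0("y", 1:9))
  g2 <- igraph::set_vertex_attr(g, "name", value = perm)
  t1 <- score_all(g); t2 <- score_all(g2)
  m <- match(perm, t2$node)
  expect_equal(t2$nim[m], t1$nim[match(paste0("x", 1:9), t1$node)],
               tolerance = 1e-12)
})

test_that("adding an edge never decreases any proximity term", {
  set.seed(6)
  for (i in 1:5) {
    g <- igraph::sample_gnp(8, 0.3)
    g <- igraph::set_vertex_attr(g, "name", value = paste0("v", 1:8))
    missing <- which(!igraph::as_adjacency_matrix(g, sparse = FALSE) &
                       upper.tri(matrix(0, 8, 8)), arr.ind = TRUE)
    if (nrow(missing) == 0L) next
    pick <- missing[sample(nrow(missing), 1L), ]
    g2 <- igraph::add_edges(g, c(pick[1], pick[2]))
    p1 <- score_all(g); p2 <- score_all(g2)
    expect_true(all(p2$proximity_term[match(p1$node, p2$node)] >=
                      p1$proximity_term - 1e-12))
  }
})

test_that("FRS keeps the upper half with the exact cardinality law", {
  set.seed(7)
  for (n in c(1, 3, 6, 7, 50)) {
    ranked <- data.frame(node = sprintf("n%02d", 1:n),
                         nim = sort(stats::runif(n)))
    frs <- select_frs(ranked)
    expect_equal(frs$n_selected, if (n %% 2 == 1) (n + 1) / 2 else n / 2)
    expect_setequal(c(frs$selected, frs$rejected), ranked$node)
    # selected nodes all score at least as high as every rejected node
    if (length(frs$rejected)) {
      expect_gte(min(ranked$nim[ranked$node %in% frs$selected]),
                 max(ranked$nim[ranked$node %in% frs$rejected]))
    }
  }
  # even-case cut value is the midpoint of the two middle scores
  ranked <- data.frame(node = c("a", "b", "c", "d"), nim = c(1, 2, 4, 8))
  expect_equal(select_frs(ranked)$cut_value, 3)
})

test_that("mean rule keeps only nodes above the average score", {
  ranked <- data.frame(node = c("a", "b", "c", "d"),
                       nim = c(0, 0, 0, 100))
  frs <- select_frs(ranked, rule = "mean")
  expect_identical(frs$selected, "d")
})

test_that("baseline selectors rank by the requested centrality", {
  star <- igraph::make_star(5, mode = "undirected")
  star <- igraph::set_vertex_attr(star, "name",
                                  value = c("c", "l1", "l2", "l3", "l4"))
  expect_true("c" %in% baseline_select(star, "degree")$selected)

  tri <- igraph::make_full_graph(3)
  tri <- igraph::set_vertex_attr(tri, "name", value = c("b", "a", "c"))
  tabc <- score_baseline(tri, "clustering_coefficient")
  expect_true(all(tabc$score == 1))
  expect_identical(tabc$node, c("a", "b", "c"))  # tie broken by id

  p5 <- igraph::make_ring(5, circular = FALSE)
  p5 <- igraph::set_vertex_attr(p5, "name", value = paste0("v", 1:5))
  tab <- score_baseline(p5, "closeness")
  expect_identical(tab$node[5], "v3")  # middle node most central

  expect_error(score_baseline(p5, "pagerank"), "valid methods")
})
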