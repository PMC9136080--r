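test_that("UET is a plain commutative, idempotent intersection", {
  expect_setequal(uet(c("A", "B", "C"), c("B", "C", "D")), c("B", "C"))
  expect_length(uet(c("A"), c("B")), 0)
  expect_setequal(uet(c("A", "B"), c("A", "B")), c("A", "B"))
  expect_setequal(uet(c("X", "Y"), c("Y", "X")), uet(c("Y", "X"), c("X", "Y")))
})

test_that("hypergeometric p matches the closed form and enumeration", {
  universe <- paste0("g", 1:20)
  coll <- gene_set_collection(list(term1 = universe[1:5]),
                              universe = universe)
  res <- enrich(universe[1:5], coll, alpha = 0.01)
  expect_equal(res$p_value, 1 / choose(20, 5), tolerance = 1e-12)
  expect_true(res$significant)

  # term spanning the whole universe is a certain event
  coll2 <- gene_set_collection(list(all = universe), universe = universe)
  res2 <- enrich(universe[1:4], coll2, alpha = 0.01)
  expect_equal(res2$p_value, 1)
  expect_false(res2$significant)

  # zero overlap terms are absent
  coll3 <- gene_set_collection(list(t = universe[6:8]), universe = universe)
  expect_equal(nrow(enrich(universe[1:3], coll3)), 0L)
})

test_that("p-values agree with exhaustive draw enumeration (universe <= 12)", {
  set.seed(400)
  for (rep in 1:12) {
    N <- sample(6:12, 1)
    universe <- paste0("u", seq_len(N))
    set <- sample(universe, sample(2:(N - 1), 1))
    q <- sample(2:(N - 1), 1)
    query <- sample(universe, q)
    k <- length(intersect(query, set))
    if (k == 0) next
    coll <- gene_set_collection(list(s = set), universe = universe)
    res <- enrich(query, coll, alpha = 0.01)
    expect_equal(res$p_value, bf_hyper_tail(universe, set, q, k),
                 tolerance = 1e-10, label = paste("rep", rep))
  }
})

test_that("query genes outside the universe are dropped and reported", {
  universe <- paste0("g", 1:10)
  coll <- gene_set_collection(list(t = universe[1:4]), universe = universe)
  res <- enrich(c(universe[1:3], "alien"), coll)
  expect_identical(attr(res, "dropped_genes"), "alien")
  expect_equal(res$query_size, 3L)
})

test_that("BH correction tightens the significant set, never the p-values", {
  set.seed(401)
  universe <- paste0("g", 1:40)
  sets <- lapply(1:8, function(i) sample(universe, 8))
  names(sets) <- paste0("t", 1:8)
  coll <- gene_set_collection(sets, universe = universe)
  query <- sample(universe, 10)
  raw <- enrich(query, coll, alpha = 0.05)
  bh <- enrich(query, coll, alpha = 0.05, correct = "BH")
  expect_equal(bh$p_value, raw$p_value)
  expect_true(all(bh$p_adjust >= bh$p_value))
  expect_true(all(bh$term_id[bh$significant] %in%
                    raw$term_id[raw$significant]))
})

test_that("coverage percent follows the printed rounding convention", {
  expect_equal(coverage(c("a", "b"), c("a", "b"))$coverage_percent, 100.00)
  ref <- paste0("t", 1:138)
  qry <- paste0("t", 1:111)
  expect_equal(coverage(qry, ref)$coverage_percent, 80.43)
  expect_equal(coverage("x", ref)$coverage_percent, 0.00)
  expect_error(coverage("x", character(0)), "empty")
})

test_that("coverage is monotone in the query term set", {
  set.seed(402)
  ref <- paste0("t", 1:30)
  qry <- sample(ref, 10)
  base <- coverage(qry, ref)$coverage_percent
  grown <- coverage(c(qry, sample(ref, 5)), ref)$coverage_percent
  expect_gte(grown, base)
})

test_that("GMT files round-trip through read and write", {
  coll <- gene_set_collection(
    list(p1 = c("a", "b", "c"), p2 = c("b", "d")),
    universe = c("a", "b", "c", "d", "e"),
    names = c(p1 = "Pathway one", p2 = "Pathway two"))
  tf <- tempfile(fileext = ".gmt")
  write_gmt(coll, tf)
  back <- read_gmt(tf)
  expect_identical(back$sets, coll$sets)
  expect_identical(unname(back$term_names["p1"]), "Pathway one")
  expect_error(read_gmt(write_tsv_fixture("only\ttwo")), "malformed")
})

test_that("frs_validation returns the three indicators", {
  universe <- paste0("g", 1:30)
  coll <- gene_set_collection(
    list(t1 = universe[1:6], t2 = universe[7:12], t3 = universe[13:18]),
    universe = universe)
  frs <- universe[1:10]
  rep_same <- frs_validation(frs, frs, list(pathways = coll, go = coll))
  expect_equal(rep_same$genes$coverage_percent, 100)
  expect_named(rep_same, c("genes", "pathways", "go"))
  # identical query and reference gene sets give identical term sets
  if (!is.na(rep_same$pathways$coverage_percent) &&
      rep_same$pathways$reference_count > 0) {
    expect_equal(rep_same$pathways$coverage_percent, 100)
  }
  rep_disjoint <- frs_validation(universe[19:25], universe[1:5],
                                 list(pathways = coll))
  expect_equal(rep_disjoint$genes$coverage_percent, 0)
})
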