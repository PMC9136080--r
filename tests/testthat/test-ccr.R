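test_that("greedy selection reproduces the hand-traced coverage path", {
  m <- list(c1 = c("t1", "t2", "t3"), c2 = c("t3", "t4"), c3 = "t5")
  eff <- paste0("t", 1:5)
  s <- ccr_select(m, eff, threshold = 0.9)
  expect_identical(s$selected, c("c1", "c2", "c3"))
  expect_equal(s$trace$cumulative_coverage, c(0.6, 0.8, 1.0))
  expect_true(s$threshold_reached)

  s2 <- ccr_select(m, eff, threshold = 0.5)
  expect_identical(s2$selected, "c1")
  expect_equal(s2$coverage, 0.6)

  tie <- ccr_select(list(c2 = c("t1", "t2"), c1 = c("t1", "t2")),
                    c("t1", "t2"))
  expect_identical(tie$selected, "c1")  # symmetric tie broken by id
  expect_equal(tie$coverage, 1.0)
})

test_that("ties prefer the larger total target set before the id", {
  m <- list(cA = c("t1", "t2", "x1", "x2", "x3"), cB = c("t1", "t2"))
  s <- ccr_select(m, c("t1", "t2"))
  expect_identical(s$selected, "cA")
})

test_that("errors and unreachable thresholds behave as contracted", {
  m <- list(c1 = "t1")
  expect_error(ccr_select(m, character(0)), "empty")
  s <- ccr_select(list(c1 = "t1"), c("t1", "t2"), threshold = 0.9)
  expect_false(s$threshold_reached)
  expect_equal(s$coverage, 0.5)
})

test_that("greedy invariants hold on random instances", {
  set.seed(100)
  for (rep in 1:200) {
    n_c <- sample(2:8, 1L)
    eff <- paste0("g", seq_len(sample(4:12, 1L)))
    m <- stats::setNames(lapply(seq_len(n_c), function(i)
      sample(eff, sample.int(length(eff), 1L))), paste0("c", seq_len(n_c)))
    s <- ccr_select(m, eff, threshold = 1.0)
    # first pick dominates on initial gain
    gains0 <- vapply(m, function(t) length(intersect(t, eff)), integer(1))
    expect_equal(s$trace$marginal_gain[1], max(gains0))
    # strict monotone coverage: every selected step adds something
    expect_true(all(s$trace$marginal_gain >= 1))
    expect_true(all(diff(s$trace$cumulative_coverage) > 0))
    # stopping contract at achievable thresholds
    achievable <- length(intersect(unlist(m), eff)) / length(eff)
    if (achievable >= 0.5) {
      expect_gte(ccr_select(m, eff, threshold = 0.5)$coverage, 0.5)
    }
  }
})

test_that("greedy prefix coverage matches a brute-force recomputation", {
  set.seed(101)
  for (rep in 1:25) {
    eff <- paste0("g", 1:10)
    m <- stats::setNames(lapply(1:6, function(i)
      sample(eff, sample.int(8, 1L))), paste0("c", 1:6))
    s <- ccr_select(m, eff, threshold = 1.0)
    # independent greedy: recompute step by step from scratch
    covered <- character(0); left <- names(m)
    for (i in seq_len(nrow(s$trace))) {
      gains <- vapply(m[left], function(t)
        length(setdiff(intersect(t, eff), covered)), integer(1))
      best <- max(gains)
      expect_equal(s$trace$marginal_gain[i], best)
      pick <- s$trace$component_id[i]
      expect_true(gains[[pick]] == best)
      covered <- union(covered, intersect(m[[pick]], eff))
      left <- setdiff(left, pick)
      expect_equal(s$trace$cumulative_coverage[i],
                   length(covered) / length(eff))
    }
    # classical greedy set-cover guarantee on enumerable instances
    if (length(intersect(unlist(m), eff)) == length(eff)) {
      sizes <- seq_along(m)
      opt <- NA
      for (k in sizes) {
        combos <- utils::combn(names(m), k, simplify = FALSE)
        if (any(vapply(combos, function(cs)
          length(intersect(unlist(m[cs]), eff)) == length(eff),
          logical(1)))) { opt <- k; break }
      }
      expect_lte(nrow(s$trace), opt * (1 + log(length(eff))))
    }
  }
})

test_that("contribution curve marks the 50% and 90% crossing ranks", {
  m <- list(c1 = c("t1", "t2", "t3"), c2 = c("t3", "t4"), c3 = "t5")
  s <- ccr_select(m, paste0("t", 1:5), threshold = 1.0)
  curve <- contribution_curve(s)
  expect_equal(attr(curve, "rank_50"), 1L)
  expect_equal(attr(curve, "rank_90"), 3L)
  expect_true(!is.unsorted(curve$cumulative_coverage))

  one <- ccr_select(list(c1 = c("t1", "t2")), c("t1", "t2"), threshold = 1.0)
  cv1 <- contribution_curve(one)
  expect_equal(nrow(cv1), 1L)
  expect_equal(cv1$cumulative_coverage, 1.0)
})

test_that("pair TSVs round-trip through read_ct_map", {
  tf <- write_tsv_fixture(c("c1\tt1", "c1\tt2", "c2\tt1", "c1\tt2"))
  m <- read_ct_map(tf)
  expect_setequal(m$c1, c("t1", "t2"))
  expect_identical(m$c2, "t1")
})
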