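mk <- function(h, start = 0L) {
  haplopanel:::new_marker(start = start, width = 1L, columns = start,
                          haplocode = as.integer(h))
}

test_that("alpha parsing accepts fractions and percentages, as a rational", {
  expect_equal(parse_alpha(0.8), list(p = 4, q = 5, value = 0.8))
  expect_equal(parse_alpha("80%")$value, 0.8)
  expect_equal(parse_alpha("0.25")$value, 0.25)
  expect_equal(parse_alpha(1)$value, 1)
  expect_error(parse_alpha(0), "alpha")
  expect_error(parse_alpha(1.2), "alpha")
  expect_error(parse_alpha(-0.1), "alpha")
})

test_that("the optimistic bound sums the strongest remaining markers", {
  expect_equal(bound_separation(4, c(4, 3, 1), 2, 1, 100), 11)
  expect_equal(bound_separation(4, c(4, 3), 2, 1, 6), 6)       # capped
  expect_equal(bound_separation(4, c(4, 3), 2, 0.5, 100), 7.5)
  # fewer markers available than slots: bound over what is left
  expect_equal(bound_separation(4, c(4), 3, 1, 100), 8)
  expect_error(bound_separation(4, c(3, 4), 2, 1, 100), "sorted")
})

test_that("branch-and-bound finds the optimal pair on the three-marker toy", {
  markers <- list(mk(c(0, 0, 1, 1), 0L), mk(c(0, 1, 1, 0), 1L),
                  mk(c(0, 1, 0, 1), 2L))
  res <- best_marker_set(markers, K = 2)
  expect_equal(res$S, 6)
  expect_equal(res$H, 1)
  expect_length(res$markers, 2)
  expect_true(res$is_exact)
  # K = 1: the strongest single marker
  res1 <- best_marker_set(markers, K = 1)
  expect_equal(res1$S, 4)
  expect_length(res1$markers, 1)
  # K >= m: all markers' combined S is the ceiling
  expect_warning(resall <- best_marker_set(markers, K = 5), "exceeds")
  all_S <- separation_index(Reduce(combine_haplocodes,
                                   marker_haplocodes(markers)))
  expect_equal(resall$S, all_S)
  expect_error(best_marker_set(list(), 2), "no markers")
  expect_error(best_marker_set(markers, 0), ">= 1")
})

test_that("fewer markers are returned when they reach the same S", {
  # any two of the first markers already separate everything; K = 3 must
  # not pad the set
  markers <- list(mk(c(0, 0, 1, 1), 0L), mk(c(0, 1, 1, 0), 1L),
                  mk(c(0, 0, 0, 1), 2L))
  res <- best_marker_set(markers, K = 3)
  expect_equal(res$S, 6)
  expect_length(res$markers, 2)
})

test_that("search equals the exhaustive oracle on random instances", {
  set.seed(73)
  for (i in 1:60) {
    n <- sample(4:10, 1)
    m <- sample(3:14, 1)
    markers <- sort_markers(reduce_markers(random_markers(n, m)))
    K <- sample.int(min(4, length(markers)), 1)
    res <- best_marker_set(markers, K = K)
    oracle <- brute_force_marker_set(markers, K = K)
    expect_equal(res$S, oracle$S)
    expect_equal(res$H, hap_diversity(res$S, n))
    # returned set really has the claimed S
    expect_equal(separation_index(Reduce(combine_haplocodes,
                                         marker_haplocodes(res$markers))),
                 res$S)
  }
})

test_that("optimal S is monotone in K and never below the best member", {
  set.seed(79)
  for (i in 1:15) {
    markers <- sort_markers(reduce_markers(random_markers(6, 8)))
    prev <- 0
    for (K in 1:min(4, length(markers))) {
      res <- best_marker_set(markers, K = K)
      expect_gte(res$S, prev)
      expect_gte(res$S, max(vapply(res$markers, `[[`, numeric(1), "S")))
      prev <- res$S
    }
  }
})

test_that("the heuristic can only understate, and scores honestly", {
  set.seed(83)
  for (i in 1:25) {
    markers <- sort_markers(reduce_markers(random_markers(8, 10)))
    K <- min(3, length(markers))
    exact <- best_marker_set(markers, K = K, alpha = 1)
    for (alpha in c(0.5, 0.8, "90%")) {
      heur <- best_marker_set(markers, K = K, alpha = alpha)
      expect_lte(heur$S, exact$S)
      expect_false(heur$is_exact)
      got <- separation_index(Reduce(combine_haplocodes,
                                     marker_haplocodes(heur$markers)))
      expect_equal(heur$S, got)
      expect_equal(heur$H, hap_diversity(got, heur$n))
    }
  }
})

test_that("pruned branches could not have beaten the incumbent at alpha = 1", {
  # on instances where the bound never prunes a branch containing the
  # optimum, node accounting must still add up: expanded nodes plus pruned
  # subtrees' roots cover every candidate extension considered
  set.seed(89)
  for (i in 1:10) {
    markers <- sort_markers(reduce_markers(random_markers(6, 9)))
    K <- min(3, length(markers))
    res <- best_marker_set(markers, K = K)
    oracle <- brute_force_marker_set(markers, K = K)
    expect_equal(res$S, oracle$S)
    expect_gte(res$nodes_pruned, 0)
    expect_gte(res$nodes_expanded, 0)
  }
})
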