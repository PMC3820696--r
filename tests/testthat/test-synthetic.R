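test_that("class counts are calibrated to the target diversity", {
  expect_identical(calibrate_counts(0, 10000), 10000L)
  pop_H <- function(counts, N) {
    (N^2 - sum(as.numeric(counts)^2)) / (N * (N - 1))
  }
  counts <- calibrate_counts(0.18, 10000, k = 2)
  expect_identical(sum(counts), 10000L)
  expect_lt(abs(pop_H(counts, 10000) - 0.18), 0.005)
  # a biallelic region cannot reach H = 0.86
  expect_error(calibrate_counts(0.86, 10000, k = 2), "unreachable")
  expect_error(calibrate_counts(0.3, 100, k = 1), "unreachable")
  # automatic class count covers the whole design range
  for (H in c(0.18, 0.2, 0.22, 0.25, 0.28, 0.33, 0.39, 0.49, 0.64, 0.86)) {
    counts <- calibrate_counts(H, 10000)
    expect_lt(abs(pop_H(counts, 10000) - H), 0.005)
  }
  # high diversity needs at least three classes
  expect_gte(length(calibrate_counts(0.86, 10000)), 3)
})

test_that("population generation is seeded and hits its target diversities", {
  specs <- list(marker_spec(1, 10, 0.2), marker_spec(21, 10, 0.45))
  p1 <- make_population_labels(500, 40, specs, seed = 5)
  p2 <- make_population_labels(500, 40, specs, seed = 5)
  expect_identical(p1$labels, p2$labels)
  expect_identical(p1$background, p2$background)
  p3 <- make_population_labels(500, 40, specs, seed = 6)
  expect_false(identical(p1$labels, p3$labels))
  expect_true(all(abs(p1$true_H - c(0.2, 0.45)) < 0.005))
  # invalid designs
  overlapping <- list(marker_spec(1, 10, 0.2), marker_spec(5, 10, 0.2))
  expect_error(make_population_labels(100, 40, overlapping, 1),
               "overlap")
  expect_error(make_population_labels(100, 20, list(marker_spec(15, 10, 0.2)),
                                      1), "within")
  expect_error(marker_spec(1, 10, 1.0), "target_H")
})

test_that("expansion realizes the calibrated diversities in actual sequences", {
  # a zero-diversity region leaves all sequences identical
  p0 <- make_population_labels(10, 100, list(marker_spec(10, 20, 0)), seed = 2)
  aln0 <- expand_population(p0)
  expect_equal(nrow(unique(aln0$chars)), 1)
  # diversities measured from the expanded matrix match the labels
  specs <- list(marker_spec(5, 12, 0.3), marker_spec(25, 16, 0.6))
  pop <- make_population_labels(300, 48, specs, seed = 9)
  aln <- expand_population(pop)
  for (r in seq_along(specs)) {
    cols <- pop$poly_positions[[r]]
    hc <- Reduce(combine_haplocodes,
                 lapply(cols, function(j) encode_column(aln$chars[, j])))
    expect_equal(hap_diversity(separation_index(hc), 300), pop$true_H[r])
    # the region's haplotypes are exactly the assigned classes
    expect_identical(hc, canonical_haplocode(pop$labels[, r]))
  }
  # FASTA writer agrees with the matrix expansion
  path <- tempfile(fileext = ".fa")
  write_population_fasta(pop, path)
  expect_identical(read_msa(path)$chars, aln$chars)
})

test_that("sampling is uniform without replacement and seeded", {
  pop <- make_population_labels(200, 30, list(marker_spec(1, 20, 0.4)),
                                seed = 3)
  s1 <- sample_population(pop, 50, seed = 11)
  s2 <- sample_population(pop, 50, seed = 11)
  expect_identical(s1$labels, s2$labels)
  expect_identical(s1$n_seqs, 50L)
  # the full population comes back as a set
  all_s <- sample_population(pop, 200, seed = 4)
  expect_identical(sort(all_s$labels[, 1]), sort(pop$labels[, 1]))
  expect_error(sample_population(pop, 1, seed = 1), "sample size")
  expect_error(sample_population(pop, 201, seed = 1), "sample size")
  # alignments can be sampled too
  aln <- expand_population(pop)
  sa <- sample_population(aln, 10, seed = 13)
  expect_identical(nrow(sa$chars), 10L)
  expect_true(all(sa$ids %in% aln$ids))
})

test_that("sample diversity estimates are unbiased and tighten with size", {
  pop <- make_population_labels(
    2000, 40,
    list(marker_spec(1, 12, 0.25), marker_spec(21, 12, 0.6)), seed = 21)
  exp <- sampling_experiment(pop, sizes = c(20, 100, 500),
                             reps = c(80, 80, 40), seed = 22)
  df <- as.data.frame(exp)
  # every unordered pair is equally likely to enter a sample, so the
  # estimator is exactly unbiased: means fall within 3 standard errors
  for (i in seq_len(nrow(df))) {
    se <- df$sd_H[i] / sqrt(df$reps[i])
    expect_lt(abs(df$mean_H[i] - df$true_H[i]), 3 * se + 1e-6)
  }
  # spread shrinks with sample size (allowing Monte-Carlo wiggle)
  for (r in unique(df$region)) {
    sds <- df$sd_H[df$region == r][order(df$size[df$region == r])]
    expect_true(all(diff(sds) < 0.02))
  }
  # sampling the whole population leaves no noise
  expect_warning(
    full <- sampling_experiment(pop, sizes = 2000, reps = 1, seed = 1),
    "single replicate")
  expect_equal(full$mean_H, pop$true_H)
  expect_equal(full$sd_H, c(0, 0))
})

test_that("the search recovers markers from every synthetic region", {
  target_H <- seq(0.1, 0.48, length.out = 10)
  specs <- lapply(seq_along(target_H), function(r) {
    marker_spec(start = (r - 1L) * 30L + 1L, width = 20L,
                target_H = target_H[r])
  })
  pop <- make_population_labels(200, 300, specs, seed = 41)
  aln <- expand_population(pop)
  markers <- sort_markers(reduce_markers(build_markers(aln, width = 1)))
  res <- best_marker_set(markers, K = 10)
  chosen_cols <- unlist(lapply(res$markers, `[[`, "columns")) + 1L
  hit <- vapply(seq_along(specs), function(r) {
    any(chosen_cols >= specs[[r]]$start &
          chosen_cols < specs[[r]]$start + specs[[r]]$width)
  }, logical(1))
  expect_true(all(hit))
})
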