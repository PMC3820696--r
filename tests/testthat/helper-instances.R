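# shared generators and independent oracles for property-style tests

random_haplocode <- function(n, k_max = n) {
  k <- sample.int(k_max, 1L)
  canonical_haplocode(sample.int(k, n, replace = TRUE))
}

# O(n^2) pair-count oracle for the separation index
brute_pair_count <- function(h) {
  sum(outer(h, h, `!=`)) / 2
}

# a random marker instance: m width-1 markers over n sequences, at least
# two haplotype classes each (monomorphic markers carry no information)
random_markers <- function(n, m, states_max = 4L) {
  lapply(seq_len(m), function(i) {
    repeat {
      h <- canonical_haplocode(
        sample.int(sample.int(states_max - 1L, 1L) + 1L, n, replace = TRUE))
      if (max(h) > 0L) break
    }
    haplopanel:::new_marker(start = i - 1L, width = 1L, columns = i - 1L,
                            haplocode = h)
  })
}

# skewed biallelic markers (rare minor allele): the optimum stays well
# below S_max, so the search has real work to do and pruning behavior is
# observable
skewed_markers <- function(n, m, minor = 0.2) {
  lapply(seq_len(m), function(i) {
    repeat {
      h <- canonical_haplocode(
        sample(0:1, n, replace = TRUE, prob = c(1 - minor, minor)))
      if (max(h) > 0L) break
    }
    haplopanel:::new_marker(start = i - 1L, width = 1L, columns = i - 1L,
                            haplocode = h)
  })
}

# exhaustive optimum: best separation index over subsets of size <= k,
# for every k = 1..K_max (independent of the branch-and-bound code path)
best_S_by_size <- function(haplocodes, K_max) {
  m <- length(haplocodes)
  best <- rep(0, min(K_max, m))
  for (size in seq_along(best)) {
    sets <- utils::combn(m, size)
    for (col in seq_len(ncol(sets))) {
      S <- separation_index(Reduce(combine_haplocodes, haplocodes[sets[, col]]))
      if (S > best[size]) best[size] <- S
    }
  }
  best <- cummax(best)
  if (K_max > m) best <- c(best, rep(best[m], K_max - m))
  best
}

marker_haplocodes <- function(markers) lapply(markers, `[[`, "haplocode")

write_toy_fasta <- function(seqs, path = tempfile(fileext = ".fa")) {
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("s", seq_along(seqs))
  writeLines(paste0(">", ids, "\n", seqs), path)
  path
}
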