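# run code with a Mersenne-Twister RNG seeded locally, restoring the
# caller's RNG state afterwards
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed, kind = "Mersenne-Twister")
  force(code)
}

# diversity of a label vector (classes need not be canonical)
labels_diversity <- function(labels) {
  n <- length(labels)
  counts <- as.numeric(tabulate(match(labels, unique(labels))))
  ((n^2 - sum(counts^2)) / 2) / max_separation(n)
}

#' Specify a synthetic marker region
#'
#' @param start 1-based start position of the region in the sequence.
#' @param width region width in bp (the study design uses 800 bp regions).
#' @param target_H desired population haplotypic diversity in `[0, 1)`.
#' @param n_haplotypes optional number of haplotype classes; the default
#'   picks the smallest count that can realize `target_H` (a biallelic
#'   region tops out near `H = 0.5`; higher diversities need more classes).
#' @return `hp_marker_spec` object.
#' @export
marker_spec <- function(start, width = 800L, target_H, n_haplotypes = NULL) {
  if (target_H < 0 || target_H >= 1) {
    stop("target_H must lie in [0, 1)", call. = FALSE)
  }
  if (width < 1L) stop("width must be >= 1", call. = FALSE)
  structure(
    list(start = as.integer(start), width = as.integer(width),
         target_H = target_H,
         n_haplotypes = if (!is.null(n_haplotypes)) as.integer(n_haplotypes)),
    class = "hp_marker_spec"
  )
}

#' The ten-region synthetic study design
#'
#' Ten non-overlapping 800 bp marker regions, evenly spaced along a
#' 16,000 bp sequence, with increasing population diversities
#' 0.18, 0.20, 0.22, 0.25, 0.28, 0.33, 0.39, 0.49, 0.64, 0.86. Together
#' with 10,000 sequences this is the design used for the sample-size
#' experiment (see [sampling_experiment()]).
#'
#' @param seq_len total sequence length in bp.
#' @return list of `hp_marker_spec` objects.
#' @export
ten_region_design <- function(seq_len = 16000L) {
  true_H <- c(0.18, 0.20, 0.22, 0.25, 0.28, 0.33, 0.39, 0.49, 0.64, 0.86)
  slot <- seq_len %/% 10L
  stopifnot(slot >= 800L)
  lapply(seq_along(true_H), function(r) {
    marker_spec(start = (r - 1L) * slot + (slot - 800L) %/% 2L + 1L,
                width = 800L, target_H = true_H[r])
  })
}

#' Calibrate haplotype class counts to a target population diversity
#'
#' Finds integer class sizes `c_1..c_k` summing to `N` whose population
#' diversity `(N^2 - sum(c_i^2)) / (N (N - 1))` lies within 0.005 of
#' `target_H`. With `k = NULL` the smallest feasible number of classes is
#' used, configured as one dominant class plus equal minor classes and
#' refined by a local integer search (single-unit transfers between
#' classes) that minimizes the calibration error.
#'
#' @param target_H desired diversity in `[0, 1)`.
#' @param N population size, `>= 2`.
#' @param k number of haplotype classes, or `NULL` for automatic.
#' @return integer vector of class counts, decreasing, summing to `N`.
#' @examples
#' calibrate_counts(0, 100)          # 100
#' counts <- calibrate_counts(0.18, 10000)
#' @export
calibrate_counts <- function(target_H, N, k = NULL) {
  N <- as.integer(N)
  if (N < 2L) stop("population size must be >= 2", call. = FALSE)
  if (target_H < 0 || target_H >= 1) {
    stop("target_H must lie in [0, 1)", call. = FALSE)
  }
  tol <- 0.005
  if (target_H <= tol && is.null(k)) return(N)

  H_of <- function(counts) {
    (N^2 - sum(as.numeric(counts)^2)) / (N * (N - 1))
  }
  balanced <- function(k) {
    base <- N %/% k
    counts <- rep(base, k)
    extra <- N - base * k
    if (extra > 0) counts[seq_len(extra)] <- counts[seq_len(extra)] + 1L
    counts
  }

  auto_k <- is.null(k)
  if (auto_k) {
    k <- 2L
    while (H_of(balanced(k)) < target_H) k <- k + 1L
  } else {
    k <- as.integer(k)
    if (k < 1L) stop("k must be >= 1", call. = FALSE)
    if (k == 1L) {
      if (target_H > tol) {
        stop("target_H = ", target_H, " unreachable with 1 haplotype class",
             call. = FALSE)
      }
      return(N)
    }
    if (H_of(balanced(k)) < target_H - tol) {
      stop("target_H = ", target_H, " unreachable with k = ", k,
           " classes (maximum ~", round(H_of(balanced(k)), 3), ")",
           call. = FALSE)
    }
  }

  solve_for_k <- function(k) {
    # dominant class + equal minors: solve c1^2 + (N - c1)^2/(k-1) = T
    T_target <- N^2 - target_H * N * (N - 1)
    a <- k / (k - 1)
    b <- -2 * N / (k - 1)
    cc <- N^2 / (k - 1) - T_target
    disc <- b^2 - 4 * a * cc
    counts <- if (disc >= 0) {
      c1 <- round((-b + sqrt(disc)) / (2 * a))
      c1 <- max(min(c1, N - (k - 1L)), ceiling(N / k))
      rest <- N - c1
      minors <- rep(rest %/% (k - 1L), k - 1L)
      extra <- rest - sum(minors)
      if (extra > 0) minors[seq_len(extra)] <- minors[seq_len(extra)] + 1L
      c(c1, minors)
    } else {
      balanced(k)
    }
    # local search: single-unit transfers while they reduce |H - target|
    err <- abs(H_of(counts) - target_H)
    repeat {
      best_move <- NULL
      for (i in seq_len(k)) {
        for (j in seq_len(k)) {
          if (i == j || counts[i] <= 1L) next
          cand <- counts
          cand[i] <- cand[i] - 1L
          cand[j] <- cand[j] + 1L
          e <- abs(H_of(cand) - target_H)
          if (e < err - 1e-15) {
            err <- e
            best_move <- cand
          }
        }
      }
      if (is.null(best_move)) break
      counts <- best_move
    }
    list(counts = counts, err = err)
  }

  if (auto_k) {
    # integer granularity may block the smallest k (relevant for small N):
    # try a few larger class counts before giving up
    best <- NULL
    for (kk in k:min(k + 8L, N)) {
      cand <- solve_for_k(kk)
      if (is.null(best) || cand$err < best$err) best <- cand
      if (best$err <= tol) break
    }
    counts <- best$counts
    err <- best$err
  } else {
    fit <- solve_for_k(k)
    counts <- fit$counts
    err <- fit$err
  }
  if (err > tol) {
    stop("could not calibrate counts within 0.005 of target_H = ", target_H,
         " (population of ", N,
         " offers too coarse a grid of attainable diversities)",
         call. = FALSE)
  }
  sort(as.integer(counts), decreasing = TRUE)
}

#' Generate a synthetic population (haplotype-label level)
#'
#' Builds the label-level representation of a synthetic population: for
#' each marker region, class counts are calibrated to the region's target
#' diversity and assigned to sequences by a seeded random permutation
#' (Mersenne-Twister). A constant random background sequence is drawn for
#' later expansion to actual sequences. All diversity estimation needs
#' only these labels; [expand_population()] / [write_population_fasta()]
#' materialize sequences when required.
#'
#' @param n_seqs number of sequences in the population.
#' @param seq_len sequence length in bp.
#' @param specs list of `hp_marker_spec` (see [marker_spec()],
#'   [ten_region_design()]); regions must be disjoint and inside the
#'   sequence.
#' @param seed integer RNG seed (mandatory: every population is
#'   reproducible from it).
#' @return object of class `hp_population`: list with `labels` (an
#'   `n_seqs x n_regions` integer matrix of haplotype class labels),
#'   `counts`, `true_H` (realized per-region population diversity),
#'   `specs`, `poly_positions` (1-based polymorphic positions per region),
#'   `background`, `n_seqs`, `seq_len`, `seed`.
#' @export
make_population_labels <- function(n_seqs, seq_len, specs, seed) {
  n_seqs <- as.integer(n_seqs)
  seq_len <- as.integer(seq_len)
  if (inherits(specs, "hp_marker_spec")) specs <- list(specs)
  starts <- vapply(specs, `[[`, integer(1), "start")
  widths <- vapply(specs, `[[`, integer(1), "width")
  if (any(starts < 1L) || any(starts + widths - 1L > seq_len)) {
    stop("marker regions must lie within the sequence", call. = FALSE)
  }
  ord <- order(starts)
  ends <- starts + widths - 1L
  if (any(starts[ord][-1L] <= ends[ord][-length(ord)])) {
    stop("marker regions must not overlap", call. = FALSE)
  }
  R <- length(specs)
  with_seed(seed, {
    background <- sample(c("A", "C", "G", "T"), seq_len, replace = TRUE)
    counts <- vector("list", R)
    labels <- matrix(NA_integer_, nrow = n_seqs, ncol = R)
    poly_positions <- vector("list", R)
    for (r in seq_len(R)) {
      sp <- specs[[r]]
      counts[[r]] <- calibrate_counts(sp$target_H, n_seqs, sp$n_haplotypes)
      k <- length(counts[[r]])
      p <- k - 1L
      if (p > sp$width) {
        stop("region ", r, " needs ", p, " polymorphic columns but is only ",
             sp$width, " bp wide", call. = FALSE)
      }
      labels[, r] <- sample(rep.int(seq_len(k), counts[[r]]))
      offsets <- if (p == 0L) integer(0)
                 else if (p == 1L) (sp$width - 1L) %/% 2L
                 else as.integer(floor(seq(0, sp$width - 1L, length.out = p)))
      poly_positions[[r]] <- sp$start + offsets
    }
    true_H <- vapply(counts, function(cnt) {
      (n_seqs^2 - sum(as.numeric(cnt)^2)) / (n_seqs * (n_seqs - 1))
    }, numeric(1))
    structure(
      list(labels = labels, counts = counts, true_H = true_H,
           specs = specs, poly_positions = poly_positions,
           background = background, n_seqs = n_seqs, seq_len = seq_len,
           seed = as.integer(seed)),
      class = "hp_population"
    )
  })
}

#' @export
print.hp_population <- function(x, ...) {
  cat("Synthetic population: ", x$n_seqs, " sequences x ", x$seq_len,
      " bp, ", ncol(x$labels), " marker region(s)\n", sep = "")
  cat("Realized population H:",
      paste(formatC(x$true_H, digits = 3, format = "f"), collapse = ", "),
      "\n")
  invisible(x)
}

# per-sequence character patterns for one region: class 1 keeps the
# background; class j > 1 mutates the (j-1)-th polymorphic column to the
# next base in the A->C->G->T cycle, so every class is a distinct haplotype
region_variant <- function(pop, r) {
  bases <- c("A", "C", "G", "T")
  pos <- pop$poly_positions[[r]]
  ref <- pop$background[pos]
  alt <- bases[(match(ref, bases)) %% 4L + 1L]
  list(positions = pos, ref = ref, alt = alt)
}

#' Expand a label-level population to an alignment matrix
#'
#' Materializes the sequences: a constant background with, in each marker
#' region, one substituted base per non-reference haplotype class (class
#' `j` differs from the background exactly at the region's `j-1`-th
#' polymorphic column). The realized per-region diversity of the matrix
#' equals the calibrated label-level diversity by construction.
#'
#' @param pop `hp_population` object.
#' @param max_cells guard on `n_seqs * seq_len` to avoid accidentally
#'   materializing a huge character matrix; use
#'   [write_population_fasta()] for large populations.
#' @return `hp_alignment` object.
#' @export
expand_population <- function(pop, max_cells = 5e6) {
  if (as.numeric(pop$n_seqs) * pop$seq_len > max_cells) {
    stop("population too large to expand in memory; ",
         "use write_population_fasta()", call. = FALSE)
  }
  chars <- matrix(rep(pop$background, each = pop$n_seqs),
                  nrow = pop$n_seqs)
  for (r in seq_len(ncol(pop$labels))) {
    v <- region_variant(pop, r)
    for (j in seq_along(v$positions)) {
      rows <- pop$labels[, r] == j + 1L
      chars[rows, v$positions[j]] <- v$alt[j]
    }
  }
  alignment_matrix(chars, ids = paste0("seq", seq_len(pop$n_seqs)))
}

#' Write a synthetic population to FASTA without materializing a matrix
#'
#' @param pop `hp_population` object.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_population_fasta <- function(pop, path) {
  seqs <- rep(paste(pop$background, collapse = ""), pop$n_seqs)
  for (r in seq_len(ncol(pop$labels))) {
    v <- region_variant(pop, r)
    for (j in seq_along(v$positions)) {
      rows <- pop$labels[, r] == j + 1L
      substr(seqs[rows], v$positions[j], v$positions[j]) <- v$alt[j]
    }
  }
  set <- Biostrings::BStringSet(seqs)
  names(set) <- paste0("seq", seq_len(pop$n_seqs))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Draw a uniform random sample from a population
#'
#' Sampling is uniform without replacement (a sample of individuals drawn
#' from the population) and deterministic given the seed; set
#' `replace = TRUE` for with-replacement draws in estimator-theory
#' experiments.
#'
#' @param pop `hp_population` or `hp_alignment` object.
#' @param size sample size, `2 <= size <= n_seqs` (without replacement).
#' @param seed integer RNG seed.
#' @param replace sample with replacement.
#' @return object of the same class as `pop`, restricted to the sample.
#' @export
sample_population <- function(pop, size, seed, replace = FALSE) {
  size <- as.integer(size)
  N <- if (inherits(pop, "hp_population")) pop$n_seqs else nrow(pop$chars)
  if (size < 2L || (!replace && size > N)) {
    stop("sample size must lie in [2, population size]", call. = FALSE)
  }
  idx <- with_seed(seed, sample.int(N, size, replace = replace))
  if (inherits(pop, "hp_population")) {
    out <- pop
    out$labels <- pop$labels[idx, , drop = FALSE]
    out$n_seqs <- size
    out$counts <- lapply(seq_len(ncol(out$labels)), function(r) {
      sort(tabulate(out$labels[, r]), decreasing = TRUE)
    })
    out
  } else {
    alignment_matrix(pop$chars[idx, , drop = FALSE],
                     ids = pop$ids[idx], reference_id = NULL)
  }
}

#' Sample-size experiment: quality of diversity estimates
#'
#' For each requested sample size, draws the requested number of uniform
#' random samples (without replacement) from the population, estimates
#' every marker region's haplotypic diversity from each sample via the
#' separation index, and reports the mean and standard deviation of the
#' estimates per region and sample size. Because every unordered pair of
#' population members is equally likely to enter a sample, the sample
#' diversity is an exactly unbiased estimator of the population diversity;
#' the experiment measures how its spread shrinks with sample size.
#'
#' @param pop `hp_population` object (label level).
#' @param sizes integer vector of sample sizes.
#' @param reps replicate counts, one per size (recycled if length 1). The
#'   default configuration uses sizes 10/50/100 with 100 replicates and
#'   size 1000 with 50 replicates.
#' @param seed integer RNG seed for the whole experiment.
#' @return data.frame of class `hp_experiment` with columns `region`,
#'   `true_H`, `size`, `mean_H`, `sd_H`, `reps`.
#' @export
sampling_experiment <- function(pop, sizes = c(10L, 50L, 100L, 1000L),
                                reps = c(100L, 100L, 100L, 50L), seed) {
  stopifnot(inherits(pop, "hp_population"))
  sizes <- as.integer(sizes)
  reps <- rep_len(as.integer(reps), length(sizes))
  if (any(reps == 1L)) {
    warning("single replicate: standard deviation reported as 0",
            call. = FALSE)
  }
  R <- ncol(pop$labels)
  out <- vector("list", length(sizes))
  with_seed(seed, {
    for (s in seq_along(sizes)) {
      est <- matrix(NA_real_, nrow = reps[s], ncol = R)
      for (rep_i in seq_len(reps[s])) {
        idx <- sample.int(pop$n_seqs, sizes[s])
        for (r in seq_len(R)) {
          est[rep_i, r] <- labels_diversity(pop$labels[idx, r])
        }
      }
      sds <- apply(est, 2L, stats::sd)
      if (reps[s] == 1L) sds <- rep(0, R)
      out[[s]] <- data.frame(
        region = seq_len(R), true_H = pop$true_H, size = sizes[s],
        mean_H = colMeans(est), sd_H = sds, reps = reps[s]
      )
    }
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("hp_experiment", "data.frame")
  res
}

#' Write a sample-size experiment report as TSV
#'
#' @param exp `hp_experiment` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_experiment_tsv <- function(exp, path) {
  utils::write.table(format(as.data.frame(exp), digits = 4), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
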