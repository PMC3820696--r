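#' Haplocodes: integer haplotype label vectors
#'
#' A *haplocode* assigns each analyzed sequence an integer haplotype label
#' for a marker (or a set of markers): two sequences carry the same label
#' exactly when they are indistinguishable at that marker. Haplocodes are
#' kept in canonical first-occurrence form (the first sequence gets label 0,
#' each previously unseen haplotype gets the next integer), so equality of
#' the information content of two markers is a plain element-wise comparison.
#'
#' @param labels an integer (or coercible) vector of haplotype labels.
#' @return `canonical_haplocode()` returns an integer vector in canonical
#'   first-occurrence form.
#' @examples
#' canonical_haplocode(c(5, 5, 2, 9))  # 0 0 1 2
#' @export
canonical_haplocode <- function(labels) {
  if (length(labels) == 0L) {
    stop("haplocode must have positive length", call. = FALSE)
  }
  match(labels, unique(labels)) - 1L
}

#' Encode one alignment column as a haplocode
#'
#' Each distinct character state (including the gap character `'-'` and
#' ambiguity codes such as `'N'`) is treated as a distinct haplotype state.
#' A monomorphic column yields the all-zero haplocode.
#'
#' @param states character vector of length `n >= 2`, one residue per
#'   analyzed sequence.
#' @return canonical haplocode (integer vector of length `n`).
#' @examples
#' encode_column(c("C", "C", "T", "T"))  # 0 0 1 1
#' encode_column(c("T", "A", "A", "T"))  # 0 1 1 0
#' @export
encode_column <- function(states) {
  if (length(states) < 2L) {
    stop("need at least two sequences to encode a column", call. = FALSE)
  }
  canonical_haplocode(as.character(states))
}

#' Combine two haplocodes
#'
#' The combination is the common refinement of the two label partitions:
#' two sequences share a label in the result iff they share labels in
#' *both* inputs. This is what observing two markers jointly does. Runs in
#' time linear in the number of sequences. The all-zero haplocode is the
#' identity element and combination is commutative, associative and
#' idempotent (up to canonical form).
#'
#' @param a,b canonical haplocodes of equal length.
#' @return canonical haplocode of the combination.
#' @examples
#' combine_haplocodes(c(0L, 0L, 1L, 1L), c(0L, 1L, 1L, 0L))  # 0 1 2 3
#' @export
combine_haplocodes <- function(a, b) {
  if (length(a) != length(b)) {
    stop("haplocodes must have equal length", call. = FALSE)
  }
  # pair each (a_i, b_i) into a single numeric key; labels are < n so the
  # product stays well inside exact double range
  key <- as.numeric(a) * (max(b) + 1) + as.numeric(b)
  match(key, unique(key)) - 1L
}

#' Haplotype class sizes of a haplocode
#'
#' @param h canonical haplocode.
#' @return integer vector of class sizes `c_i` (one per haplotype).
#' @export
haplotype_counts <- function(h) {
  tabulate(as.integer(h) + 1L)
}

#' Separation index of a haplocode
#'
#' The separation index `S` counts the unordered pairs of sequences that a
#' marker (set) assigns to different haplotypes. With class sizes `c_i` and
#' `n` sequences, `S = (n^2 - sum(c_i^2)) / 2`, an exact integer: diversity
#' bookkeeping can be done wholly in integers, and only converted to a
#' diversity on reporting. Its maximum is `n(n-1)/2`, reached when every
#' sequence is its own haplotype.
#'
#' @param h canonical haplocode.
#' @return the separation index as an integer-valued numeric.
#' @examples
#' separation_index(c(0L, 0L, 1L, 1L))  # 4
#' separation_index(c(0L, 1L, 2L, 3L))  # 6
#' @export
separation_index <- function(h) {
  n <- length(h)
  counts <- as.numeric(haplotype_counts(h))
  (n^2 - sum(counts^2)) / 2
}

#' Maximum separation index for a sample of size n
#'
#' @param n sample size.
#' @return `n(n-1)/2`.
#' @export
max_separation <- function(n) {
  n * (n - 1) / 2
}

#' Haplotypic diversity from a separation index
#'
#' Converts a separation index to the haplotypic diversity
#' `H = S / (n(n-1)/2)`: the probability that two individuals drawn at
#' random (without replacement) from the sample differ at the marker set.
#' Algebraically identical to Nei's estimator with the small-sample
#' correction (see [nei_diversity()]).
#'
#' @param S separation index, `0 <= S <= n(n-1)/2`.
#' @param n sample size, `>= 2`.
#' @return diversity in `[0, 1]`.
#' @examples
#' hap_diversity(4, 4)  # 2/3
#' @export
hap_diversity <- function(S, n) {
  if (n < 2) stop("sample size must be at least 2", call. = FALSE)
  smax <- max_separation(n)
  if (S < 0 || S > smax) {
    stop("separation index outside [0, n(n-1)/2]", call. = FALSE)
  }
  S / smax
}

#' Nei's haplotypic diversity estimator
#'
#' `H = n/(n-1) * (1 - sum(p_i^2))` for haplotype frequencies `p_i` in a
#' sample of size `n`. Serves as an independent check of the separation
#' index route: for class sizes `c_i = p_i * n` the two are identical.
#'
#' @param frequencies haplotype frequency vector, summing to 1.
#' @param n sample size, `>= 2`.
#' @return diversity in `[0, 1]`.
#' @examples
#' nei_diversity(c(0.5, 0.5), 4)  # 2/3
#' @export
nei_diversity <- function(frequencies, n) {
  if (n < 2) stop("sample size must be at least 2", call. = FALSE)
  if (any(frequencies < 0) || abs(sum(frequencies) - 1) > 1e-9) {
    stop("frequencies must be non-negative and sum to 1", call. = FALSE)
  }
  n / (n - 1) * (1 - sum(frequencies^2))
}
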