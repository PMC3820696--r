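#' Is one marker informationally subsumed by another?
#'
#' Marker `a` is subsumed by marker `b` when combining the two haplocodes
#' yields `b`'s haplocode unchanged: everything `a` separates, `b` already
#' separates, so `a` contributes nothing beyond `b`. Equal haplocodes
#' subsume each other.
#'
#' @param a,b `hp_marker` objects with canonical haplocodes of equal
#'   length.
#' @return logical.
#' @export
is_subsumed <- function(a, b) {
  identical(combine_haplocodes(a$haplocode, b$haplocode),
            as.integer(b$haplocode))
}

#' Remove redundant and subsumed markers
#'
#' Two reductions are applied before searching: (1) markers with identical
#' haplocodes are collapsed to the one with the smallest start (duplicates
#' are found by hashing the canonical label vectors); (2) a marker whose
#' information is a subset of another retained marker's information is
#' dropped (pairwise subsumption test). The reduction never changes the
#' optimal separation index attainable by any subset size, it only shrinks
#' the search space. Idempotent.
#'
#' @param markers list of `hp_marker` objects.
#' @return reduced list of markers, in the original (start) order.
#' @export
reduce_markers <- function(markers) {
  if (length(markers) <= 1L) return(markers)
  ord <- order(vapply(markers, `[[`, integer(1), "start"))
  markers <- markers[ord]
  key <- vapply(markers, function(m) paste(m$haplocode, collapse = ","),
                character(1))
  markers <- markers[!duplicated(key)]
  m <- length(markers)
  keep <- rep(TRUE, m)
  for (i in seq_len(m)) {
    if (!keep[i]) next
    for (j in seq_len(m)) {
      if (i == j || !keep[j]) next
      if (is_subsumed(markers[[i]], markers[[j]])) {
        keep[i] <- FALSE
        break
      }
    }
  }
  markers[keep]
}

#' Sort markers by separation index
#'
#' Decreasing separation index, ties broken by start position ascending.
#' The decreasing order is what makes the branch-and-bound upper bound
#' valid: the strongest markers still available are always next in line.
#'
#' @param markers list of `hp_marker` objects.
#' @return sorted list.
#' @export
sort_markers <- function(markers) {
  if (length(markers) <= 1L) return(markers)
  S <- vapply(markers, `[[`, numeric(1), "S")
  start <- vapply(markers, `[[`, integer(1), "start")
  markers[order(-S, start)]
}
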