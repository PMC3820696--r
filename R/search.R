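#' Parse a heuristic parameter alpha
#'
#' Accepts a fraction (`0.8`), a percentage string (`"80%"`), or a numeric
#' string. Internally alpha is held as a reduced rational `p/q` with
#' `q <= 10000` (alpha is rounded to four decimals) so all bound
#' comparisons during the search can be evaluated with exact integer
#' cross-multiplication.
#'
#' @param alpha numeric in `(0, 1]` or a string like `"80%"`.
#' @return list with `p`, `q` (integers) and `value = p/q`.
#' @export
parse_alpha <- function(alpha) {
  if (is.character(alpha)) {
    s <- trimws(alpha)
    if (grepl("%$", s)) {
      alpha <- as.numeric(sub("%$", "", s)) / 100
    } else {
      alpha <- as.numeric(s)
    }
  }
  if (!is.finite(alpha) || alpha <= 0 || alpha > 1) {
    stop("alpha must lie in (0, 1]", call. = FALSE)
  }
  q <- 10000
  p <- round(alpha * q)
  if (p == 0) stop("alpha must lie in (0, 1]", call. = FALSE)
  g <- gcd_int(p, q)
  list(p = p / g, q = q / g, value = (p / g) / (q / g))
}

gcd_int <- function(a, b) {
  while (b != 0) {
    t <- b
    b <- a %% b
    a <- t
  }
  a
}

#' Upper bound on the separation index of an extended marker set
#'
#' If the current set separates `S_current` pairs and up to `k_remaining`
#' markers may still be added from a pool whose separation indices are
#' sorted decreasingly, then — treating markers as if they were
#' independent — the extended set can separate at most
#' `S_current + alpha * (sum of the k_remaining largest remaining S)`,
#' capped at `S_max` (no set separates more than all pairs). With
#' `alpha = 1` this is the exact (if weak) bound used for optimal search;
#' `alpha < 1` assumes each prospective marker contributes only a fraction
#' of its separation index, pruning more aggressively at the risk of
#' missing the optimum.
#'
#' @param S_current separation index of the current set.
#' @param remaining_S numeric vector of remaining markers' separation
#'   indices, sorted decreasingly.
#' @param k_remaining number of markers that may still be added.
#' @param alpha heuristic parameter in `(0, 1]` (numeric or `"NN%"`).
#' @param S_max maximum separation index `n(n-1)/2`.
#' @return the bound (numeric).
#' @examples
#' bound_separation(4, c(4, 3, 1), 2, 1, 100)    # 11
#' bound_separation(4, c(4, 3), 2, 1, 6)         # 6 (capped)
#' bound_separation(4, c(4, 3), 2, 0.5, 100)     # 7.5
#' @export
bound_separation <- function(S_current, remaining_S, k_remaining, alpha = 1,
                             S_max) {
  a <- parse_alpha(alpha)
  if (is.unsorted(rev(remaining_S))) {
    stop("remaining_S must be sorted decreasingly", call. = FALSE)
  }
  take <- min(k_remaining, length(remaining_S))
  min(S_max, S_current + a$value * sum(remaining_S[seq_len(take)]))
}

#' Find the marker set with maximal separation index
#'
#' Depth-first branch-and-bound search over subsets of at most `K` markers
#' for the subset whose combined haplocode separates the most sequence
#' pairs (equivalently, has maximal haplotypic diversity / exclusion
#' capacity). Markers are first sorted by decreasing separation index;
#' the search extends the current set with markers further down the list
#' and prunes any branch whose optimistic bound (see [bound_separation()])
#' cannot strictly beat the incumbent. The incumbent is initialized by a
#' greedy pass (best single marker, extended by the best immediate
#' improvement), which only tightens pruning. With `alpha = 1` the
#' returned separation index is globally optimal over all subsets of size
#' `<= K`; with `alpha < 1` the search is heuristic and may understate the
#' optimum, but the reported `S` and `H` are always the true values of the
#' returned set — the heuristic affects search only, never scoring.
#'
#' Bound comparisons are carried out in exact integer arithmetic (alpha as
#' a rational `p/q`), so search decisions are bit-reproducible.
#'
#' `K` is a maximum: with `prefer_smaller = TRUE` (default) a smaller set
#' achieving the same separation index is preferred. Among equal solutions
#' the first one encountered in sorted order is kept, making the result
#' deterministic.
#'
#' @param markers list of `hp_marker` objects, ideally already passed
#'   through [reduce_markers()]; they are sorted internally.
#' @param K maximum set size, `>= 1`.
#' @param alpha heuristic parameter in `(0, 1]`, numeric or `"NN%"`;
#'   `1` gives exact search.
#' @param prefer_smaller prefer fewer markers at equal separation index.
#' @return object of class `hp_search_result`: list with `markers` (the
#'   chosen subset), `S`, `H`, `n`, `K`, `alpha`, `is_exact`,
#'   `nodes_expanded` and `nodes_pruned`.
#' @export
best_marker_set <- function(markers, K, alpha = 1, prefer_smaller = TRUE) {
  if (!length(markers)) stop("no markers to search", call. = FALSE)
  K <- as.integer(K)
  if (K < 1L) stop("K must be >= 1", call. = FALSE)
  if (K > length(markers)) {
    warning("K exceeds the number of markers; using all ", length(markers),
            call. = FALSE)
    K <- length(markers)
  }
  a <- parse_alpha(alpha)
  markers <- sort_markers(markers)
  m <- length(markers)
  n <- length(markers[[1L]]$haplocode)
  S_max <- max_separation(n)
  hc <- lapply(markers, `[[`, "haplocode")
  S <- vapply(markers, `[[`, numeric(1), "S")
  cs <- cumsum(S)
  # sum of S over sorted positions i .. i+k-1 (truncated at m)
  topsum <- function(i, k) {
    hi <- min(m, i + k - 1L)
    cs[hi] - if (i > 1L) cs[i - 1L] else 0
  }

  # greedy warm start: best single marker, then best immediate extension
  g_idx <- 1L
  g_hc <- hc[[1L]]
  g_S <- S[1L]
  while (length(g_idx) < K && g_S < S_max) {
    cand <- setdiff(seq_len(m), g_idx)
    comb_S <- vapply(cand, function(j) {
      separation_index(combine_haplocodes(g_hc, hc[[j]]))
    }, numeric(1))
    if (max(comb_S) <= g_S) break
    j <- cand[which.max(comb_S)]
    g_hc <- combine_haplocodes(g_hc, hc[[j]])
    g_S <- max(comb_S)
    g_idx <- c(g_idx, j)
  }

  env <- new.env(parent = emptyenv())
  env$best_S <- g_S
  env$best_idx <- g_idx
  env$expanded <- 0
  env$pruned <- 0

  better <- function(S_new, size_new) {
    S_new > env$best_S ||
      (prefer_smaller && S_new == env$best_S &&
         size_new < length(env$best_idx))
  }

  dfs <- function(cur_hc, cur_S, begin, k_left, idx) {
    i <- begin
    while (i <= m) {
      # prune unless alpha-scaled bound strictly beats the incumbent:
      # cur_S + (p/q) * topsum > best  <=>  q*cur_S + p*topsum > q*best
      if (env$best_S >= S_max ||
          a$q * cur_S + a$p * topsum(i, k_left) <= a$q * env$best_S) {
        env$pruned <- env$pruned + (m - i + 1L)
        break
      }
      new_hc <- combine_haplocodes(cur_hc, hc[[i]])
      new_S <- separation_index(new_hc)
      env$expanded <- env$expanded + 1
      new_idx <- c(idx, i)
      if (better(new_S, length(new_idx))) {
        env$best_S <- new_S
        env$best_idx <- new_idx
      }
      if (k_left > 1L && i < m && new_S < S_max) {
        dfs(new_hc, new_S, i + 1L, k_left - 1L, new_idx)
      }
      i <- i + 1L
    }
  }
  dfs(rep(0L, n), 0, 1L, K, integer(0))

  chosen <- markers[env$best_idx]
  final_hc <- Reduce(combine_haplocodes, lapply(chosen, `[[`, "haplocode"))
  final_S <- separation_index(final_hc)
  structure(
    list(markers = chosen, S = final_S, H = hap_diversity(final_S, n),
         n = n, K = K, alpha = a$value, is_exact = a$value == 1,
         haplocode = final_hc,
         nodes_expanded = env$expanded, nodes_pruned = env$pruned),
    class = "hp_search_result"
  )
}

#' @export
print.hp_search_result <- function(x, ...) {
  cat("Marker set: ", length(x$markers), " marker(s), S = ", format(x$S),
      " of ", format(max_separation(x$n)), ", H = ",
      formatC(x$H, digits = 4, format = "f"), "\n", sep = "")
  cat("Search: alpha = ", x$alpha,
      if (x$is_exact) " (exact)" else " (heuristic)",
      ", ", x$nodes_expanded, " nodes expanded, ", x$nodes_pruned,
      " pruned\n", sep = "")
  invisible(x)
}

#' Exhaustive search over marker subsets
#'
#' Enumerates every subset of size `1..K` and returns the subset with
#' maximal separation index (ties: fewer markers, then lexicographically
#' first in sorted order). Intended as a verification oracle for
#' [best_marker_set()] on small instances; refuses large instances unless
#' `force = TRUE`.
#'
#' @param markers list of `hp_marker` objects.
#' @param K maximum subset size.
#' @param force allow instances beyond the `m <= 25`, `K <= 5` guard.
#' @return `hp_search_result` (node counters refer to evaluated subsets).
#' @export
brute_force_marker_set <- function(markers, K, force = FALSE) {
  if (!length(markers)) stop("no markers to search", call. = FALSE)
  K <- as.integer(min(K, length(markers)))
  if (K < 1L) stop("K must be >= 1", call. = FALSE)
  m <- length(markers)
  if (!force && (m > 25L || K > 5L)) {
    stop("instance too large for exhaustive search (m <= 25, K <= 5); ",
         "use force = TRUE to override", call. = FALSE)
  }
  markers <- sort_markers(markers)
  hc <- lapply(markers, `[[`, "haplocode")
  n <- length(hc[[1L]])
  best_S <- -1
  best_idx <- integer(0)
  evaluated <- 0
  for (size in seq_len(K)) {
    sets <- utils::combn(m, size)
    for (col in seq_len(ncol(sets))) {
      idx <- sets[, col]
      S <- separation_index(Reduce(combine_haplocodes, hc[idx]))
      evaluated <- evaluated + 1
      if (S > best_S) {
        best_S <- S
        best_idx <- idx
      }
    }
  }
  chosen <- markers[best_idx]
  final_hc <- Reduce(combine_haplocodes, hc[best_idx])
  structure(
    list(markers = chosen, S = best_S, H = hap_diversity(best_S, n),
         n = n, K = K, alpha = 1, is_exact = TRUE, haplocode = final_hc,
         nodes_expanded = evaluated, nodes_pruned = 0),
    class = "hp_search_result"
  )
}
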