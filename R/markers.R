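#' Find polymorphic alignment columns
#'
#' Returns the (0-based) columns showing at least two distinct states among
#' the analyzed sequences, after dropping the reference row and any
#' excluded columns. By default every distinct character (gap `'-'`,
#' ambiguity codes, ...) counts as a state; in strict mode columns
#' containing characters outside `A/C/G/T/-` are dropped entirely.
#'
#' @param aln `hp_alignment` object.
#' @param strict drop columns containing non-`ACGT-` characters.
#' @return sorted integer vector of 0-based column indices.
#' @export
find_polymorphic_columns <- function(aln, strict = FALSE) {
  m <- aln$chars[analysis_rows(aln), , drop = FALSE]
  keep <- rep(TRUE, ncol(m))
  if (length(aln$excluded_columns)) keep[aln$excluded_columns + 1L] <- FALSE
  if (strict) {
    bad <- apply(m, 2L, function(col) any(!col %in% c("A", "C", "G", "T", "-")))
    keep <- keep & !bad
  }
  poly <- vapply(seq_len(ncol(m)),
                 function(j) keep[j] && length(unique(m[, j])) > 1L,
                 logical(1))
  which(poly) - 1L
}

# marker constructor: start/columns are 0-based alignment coordinates
new_marker <- function(start, width, columns, haplocode) {
  structure(
    list(start = as.integer(start), width = as.integer(width),
         columns = as.integer(columns), haplocode = haplocode,
         S = separation_index(haplocode)),
    class = "hp_marker"
  )
}

#' @export
print.hp_marker <- function(x, ...) {
  cat("Marker [", x$start + 1L, "-", x$start + x$width, "] (1-based), ",
      length(x$columns), " polymorphic column(s), S = ", format(x$S),
      "\n", sep = "")
  invisible(x)
}

#' Build candidate markers of a given width
#'
#' A marker is an alignment window of `width` columns together with the
#' haplocode combining its polymorphic columns. For `width = 1` there is
#' one marker per polymorphic column. For wider markers, windows are
#' anchored at polymorphic columns and slid to cover maximal runs of
#' polymorphic columns; windows whose polymorphic-column set is contained
#' in another window's set are dropped (a contained marker can never carry
#' more information), so overlapping windows survive only when each covers
#' a column the other does not.
#'
#' @param aln `hp_alignment` object (reference removed from analysis,
#'   exclusions already applied).
#' @param width marker width in alignment columns, `>= 1`.
#' @param strict see [find_polymorphic_columns()].
#' @return list of `hp_marker` objects (possibly empty).
#' @export
build_markers <- function(aln, width = 1L, strict = FALSE) {
  width <- as.integer(width)
  L <- ncol(aln$chars)
  if (width < 1L) stop("width must be >= 1", call. = FALSE)
  if (width > L) stop("width exceeds alignment length", call. = FALSE)
  poly <- find_polymorphic_columns(aln, strict = strict)
  if (!length(poly)) {
    message("no polymorphic columns found")
    return(list())
  }
  m <- aln$chars[analysis_rows(aln), , drop = FALSE]
  col_hc <- lapply(poly, function(j) encode_column(m[, j + 1L]))
  names(col_hc) <- as.character(poly)

  if (width == 1L) {
    return(lapply(seq_along(poly), function(i) {
      new_marker(poly[i], 1L, poly[i], col_hc[[i]])
    }))
  }

  # for each polymorphic column i, the furthest polymorphic column index
  # reachable by a width-w window starting at poly[i]
  k <- length(poly)
  endidx <- vapply(seq_len(k), function(i) {
    max(which(poly < poly[i] + width))
  }, integer(1))
  # keep only maximal runs: run i is contained in run i-1 iff its end does
  # not extend past the previous run's end
  keep <- c(TRUE, endidx[-1L] > endidx[-k])
  lapply(which(keep), function(i) {
    cols <- poly[i:endidx[i]]
    # slide the window so it stays inside the alignment and covers cols
    start <- max(0L, min(poly[i], L - width))
    hc <- Reduce(combine_haplocodes, col_hc[as.character(cols)])
    new_marker(start, width, cols, hc)
  })
}
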