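#' Read an aligned FASTA file into an alignment matrix
#'
#' Reads a multiple sequence alignment in FASTA format. All records must
#' have identical length (it is an alignment, not a sequence set). Residues
#' are uppercased and `U` is mapped to `T`; gaps must be `'-'` and are kept.
#' A reference record (e.g. the rCRS for human mtDNA) may be named: it is
#' retained for coordinate indexing but removed from every diversity
#' computation.
#'
#' @param path path to an aligned FASTA file.
#' @param reference_id optional identifier of a reference record used only
#'   for position indexing.
#' @return an object of class `hp_alignment`: a list with `ids`, `chars`
#'   (an `n x L` uppercase character matrix with rownames set to `ids`),
#'   `reference_id` (or `NULL`) and `excluded_columns` (0-based integer
#'   vector, initially empty).
#' @export
read_msa <- function(path, reference_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  # FASTA headers: identifier is the first whitespace-delimited token
  ids <- sub("\\s.*$", "", names(seqs))
  alignment_matrix(as.character(seqs), ids = ids, reference_id = reference_id)
}

#' Build an alignment matrix from sequences or a character matrix
#'
#' @param x character vector of aligned sequences (one string each) or an
#'   `n x L` character matrix.
#' @param ids sequence identifiers (unique).
#' @param reference_id optional reference identifier, must be one of `ids`.
#' @return `hp_alignment` object; see [read_msa()].
#' @export
alignment_matrix <- function(x, ids = NULL, reference_id = NULL) {
  if (is.matrix(x)) {
    chars <- x
    if (is.null(ids)) ids <- rownames(x)
  } else {
    if (is.null(ids)) ids <- names(x)
    widths <- nchar(x)
    if (length(unique(widths)) > 1L) {
      stop("alignment error: sequences have unequal lengths (",
           paste(unique(widths), collapse = ", "), ")", call. = FALSE)
    }
    chars <- do.call(rbind, strsplit(x, "", fixed = TRUE))
  }
  if (is.null(ids)) ids <- paste0("seq", seq_len(nrow(chars)))
  ids <- as.character(ids)
  if (anyDuplicated(ids)) {
    stop("duplicate sequence identifiers: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  if (length(ids) != nrow(chars)) {
    stop("number of identifiers does not match number of sequences",
         call. = FALSE)
  }
  chars <- chartr("U", "T", toupper(chars))
  rownames(chars) <- ids
  n_analysis <- nrow(chars) - (!is.null(reference_id))
  if (n_analysis < 2L) {
    stop("need at least 2 sequences (excluding the reference)",
         call. = FALSE)
  }
  if (!is.null(reference_id) && !reference_id %in% ids) {
    stop("reference_id '", reference_id, "' not found among sequence ids",
         call. = FALSE)
  }
  structure(
    list(ids = ids, chars = chars, reference_id = reference_id,
         excluded_columns = integer(0)),
    class = "hp_alignment"
  )
}

#' @export
print.hp_alignment <- function(x, ...) {
  cat("Alignment: ", nrow(x$chars), " sequences x ", ncol(x$chars),
      " columns\n", sep = "")
  if (!is.null(x$reference_id)) {
    cat("Reference (indexing only):", x$reference_id, "\n")
  }
  if (length(x$excluded_columns)) {
    cat("Excluded columns:", length(x$excluded_columns), "\n")
  }
  invisible(x)
}

#' Write an alignment back to FASTA
#'
#' @param aln `hp_alignment` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_msa <- function(aln, path) {
  seqs <- apply(aln$chars, 1L, paste, collapse = "")
  set <- Biostrings::BStringSet(seqs)
  names(set) <- aln$ids
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

# logical index of rows entering diversity computations
analysis_rows <- function(aln) {
  if (is.null(aln$reference_id)) rep(TRUE, length(aln$ids))
  else aln$ids != aln$reference_id
}

#' Map alignment columns to reference coordinates
#'
#' Builds the column-to-position mapping induced by a reference row:
#' each column where the reference is ungapped maps to the 1-based count of
#' ungapped reference characters up to and including it (rCRS-style
#' numbering); columns where the reference carries a gap are labelled as
#' insertions after the preceding reference position (`"p+k"` for the k-th
#' inserted column after position p).
#'
#' @param aln `hp_alignment` object.
#' @param reference_id identifier of the reference row; defaults to the
#'   alignment's `reference_id`.
#' @return object of class `hp_ref_index`: list with `position` (integer
#'   vector, one entry per column, `NA` at insertion columns), `after`
#'   (integer, the reference position an insertion column follows; `NA` for
#'   ungapped columns) and `label` (character, e.g. `"73"` or `"73+2"`).
#' @export
build_reference_index <- function(aln, reference_id = aln$reference_id) {
  if (is.null(reference_id)) stop("no reference_id given", call. = FALSE)
  if (!reference_id %in% aln$ids) {
    stop("reference_id '", reference_id, "' not found", call. = FALSE)
  }
  ref <- aln$chars[match(reference_id, aln$ids), ]
  nongap <- ref != "-"
  if (!any(nongap)) {
    stop("reference sequence is all gaps: no mappable positions",
         call. = FALSE)
  }
  pos <- ifelse(nongap, cumsum(nongap), NA_integer_)
  after <- ifelse(nongap, NA_integer_, cumsum(nongap))
  # k-th insertion column after a given position
  ins_k <- stats::ave(as.integer(!nongap), cumsum(nongap), FUN = cumsum)
  label <- ifelse(nongap, as.character(pos), paste0(after, "+", ins_k))
  structure(
    list(position = as.integer(pos), after = as.integer(after),
         label = label, reference_id = reference_id),
    class = "hp_ref_index"
  )
}

#' Parse a plain-text exclusion list
#'
#' One entry per line: either a single 1-based position (`"3107"`) or an
#' inclusive range (`"16024-16365"`). Blank lines and lines starting with
#' `#` are ignored.
#'
#' @param path path to the exclusion file.
#' @return object of class `hp_exclusions`: list with `positions` (integer
#'   vector) and `ranges` (two-column integer matrix `start`, `end`).
#' @export
read_exclusions <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  is_range <- grepl("-", lines, fixed = TRUE)
  positions <- as.integer(lines[!is_range])
  ranges <- if (any(is_range)) {
    parts <- strsplit(lines[is_range], "-", fixed = TRUE)
    t(vapply(parts, function(p) as.integer(p[1:2]), integer(2)))
  } else {
    matrix(integer(0), ncol = 2)
  }
  colnames(ranges) <- c("start", "end")
  exclusion_spec(positions, ranges)
}

#' Construct an exclusion specification
#'
#' @param positions integer vector of 1-based positions.
#' @param ranges two-column matrix (or NULL) of 1-based inclusive ranges.
#' @return `hp_exclusions` object.
#' @export
exclusion_spec <- function(positions = integer(0), ranges = NULL) {
  positions <- as.integer(positions)
  if (is.null(ranges)) ranges <- matrix(integer(0), ncol = 2)
  ranges <- matrix(as.integer(ranges), ncol = 2,
                   dimnames = list(NULL, c("start", "end")))
  if (any(positions < 1L) || any(ranges < 1L)) {
    stop("exclusion coordinates must be >= 1", call. = FALSE)
  }
  if (nrow(ranges) && any(ranges[, 1] > ranges[, 2])) {
    stop("exclusion ranges must have start <= end", call. = FALSE)
  }
  structure(list(positions = positions, ranges = ranges),
            class = "hp_exclusions")
}

#' Apply position exclusions to an alignment
#'
#' Marks alignment columns as excluded from analysis. When a reference
#' index is supplied, coordinates are interpreted as 1-based reference
#' positions (e.g. rCRS positions for mtDNA disease sites or hypervariable
#' regions) and insertion columns attached to an excluded position are
#' excluded along with it; without an index, coordinates are 1-based
#' alignment columns. Positions beyond the reference (or alignment) length
#' are skipped with a warning, so generic disease lists can be applied to
#' partial alignments. Idempotent.
#'
#' @param aln `hp_alignment` object.
#' @param spec `hp_exclusions` object (see [exclusion_spec()]).
#' @param index optional `hp_ref_index` from [build_reference_index()].
#' @return the alignment with `excluded_columns` updated (0-based, sorted).
#' @export
apply_exclusions <- function(aln, spec, index = NULL) {
  pos <- spec$positions
  if (nrow(spec$ranges)) {
    pos <- c(pos, unlist(lapply(seq_len(nrow(spec$ranges)), function(i) {
      seq.int(spec$ranges[i, 1], spec$ranges[i, 2])
    })))
  }
  pos <- unique(sort(pos))
  if (!length(pos)) return(aln)
  if (is.null(index)) {
    max_pos <- ncol(aln$chars)
    oob <- pos > max_pos
    if (any(oob)) {
      warning(sum(oob), " excluded position(s) beyond alignment length ",
              max_pos, " were skipped", call. = FALSE)
    }
    cols0 <- pos[!oob] - 1L
  } else {
    max_pos <- max(index$position, na.rm = TRUE)
    oob <- pos > max_pos
    if (any(oob)) {
      warning(sum(oob), " excluded position(s) beyond reference length ",
              max_pos, " were skipped", call. = FALSE)
    }
    pos <- pos[!oob]
    hit <- index$position %in% pos | index$after %in% pos
    cols0 <- which(hit) - 1L
  }
  aln$excluded_columns <-
    sort(unique(c(aln$excluded_columns, as.integer(cols0))))
  aln
}
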