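#' Run the full marker-selection pipeline on an alignment
#'
#' Reads (or accepts) an aligned FASTA, applies optional position
#' exclusions, extracts candidate markers of the requested width, removes
#' redundant/subsumed markers, and runs the branch-and-bound search for
#' the marker set of size at most `K` with maximal haplotypic diversity.
#' Optionally writes a TSV report (one row per chosen marker with its
#' position, width, separation index and individual diversity, plus a
#' summary block) and a machine-readable JSON twin carrying the same
#' numbers.
#'
#' @param msa path to an aligned FASTA file, or an `hp_alignment` object.
#' @param K maximum marker-set size.
#' @param width marker width in alignment columns.
#' @param alpha heuristic parameter in `(0, 1]` (numeric or `"NN%"`);
#'   1 = exact search.
#' @param reference_id optional reference record (used for coordinate
#'   reporting only, removed from analysis).
#' @param exclude optional `hp_exclusions` object or path to a plain-text
#'   exclusion list (see [read_exclusions()]).
#' @param strict_bases drop columns containing non-`ACGT-` characters.
#' @param prefer_smaller prefer fewer markers at equal diversity.
#' @param out_prefix if given, write `<prefix>.tsv` and `<prefix>.json`.
#' @return list of class `hp_find_result` with elements `search`
#'   (`hp_search_result`), `table` (per-marker data.frame), `summary`
#'   (named list), and `alignment`.
#' @export
run_find <- function(msa, K, width = 1L, alpha = 1, reference_id = NULL,
                     exclude = NULL, strict_bases = FALSE,
                     prefer_smaller = TRUE, out_prefix = NULL) {
  aln <- if (inherits(msa, "hp_alignment")) msa
         else read_msa(msa, reference_id = reference_id)
  if (!is.null(reference_id)) aln$reference_id <- reference_id
  index <- if (!is.null(aln$reference_id)) build_reference_index(aln)
  if (!is.null(exclude)) {
    spec <- if (inherits(exclude, "hp_exclusions")) exclude
            else read_exclusions(exclude)
    aln <- apply_exclusions(aln, spec, index = index)
  }
  candidates <- build_markers(aln, width = width, strict = strict_bases)
  if (!length(candidates)) {
    stop("no candidate markers: alignment has no usable polymorphic columns",
         call. = FALSE)
  }
  reduced <- reduce_markers(candidates)
  res <- best_marker_set(reduced, K = K, alpha = alpha,
                         prefer_smaller = prefer_smaller)

  pos_label <- function(mk) {
    cols1 <- mk$columns + 1L
    labs <- if (!is.null(index)) index$label[cols1] else as.character(cols1)
    paste(labs, collapse = ",")
  }
  n <- res$n
  table <- data.frame(
    position = vapply(res$markers, pos_label, character(1)),
    start = vapply(res$markers, function(m) m$start + 1L, integer(1)),
    width = vapply(res$markers, `[[`, integer(1), "width"),
    S = vapply(res$markers, `[[`, numeric(1), "S"),
    H = vapply(res$markers, function(m) hap_diversity(m$S, n), numeric(1))
  )
  summary <- list(
    n_sequences = n,
    coordinate_system = if (!is.null(index)) "reference" else "alignment",
    n_markers_candidates = length(candidates),
    n_markers_reduced = length(reduced),
    K = res$K, alpha = res$alpha, is_exact = res$is_exact,
    n_markers_chosen = length(res$markers),
    combined_S = res$S, S_max = max_separation(n), combined_H = res$H,
    nodes_expanded = res$nodes_expanded, nodes_pruned = res$nodes_pruned
  )
  out <- structure(list(search = res, table = table, summary = summary,
                        alignment = aln),
                   class = "hp_find_result")
  if (!is.null(out_prefix)) write_find_report(out, out_prefix)
  out
}

#' @export
print.hp_find_result <- function(x, ...) {
  print(x$search)
  cat("Markers (", x$summary$coordinate_system, " coordinates):\n", sep = "")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Write TSV + JSON reports for a marker search
#'
#' @param result `hp_find_result` from [run_find()].
#' @param prefix output path prefix; writes `<prefix>.tsv` and
#'   `<prefix>.json`.
#' @return character vector of the two paths, invisibly.
#' @export
write_find_report <- function(result, prefix) {
  tsv <- paste0(prefix, ".tsv")
  json <- paste0(prefix, ".json")
  con <- file(tsv, "w")
  on.exit(close(con))
  for (key in names(result$summary)) {
    cat("# ", key, " = ", format(result$summary[[key]], digits = 12),
        "\n", sep = "", file = con)
  }
  utils::write.table(result$table, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(
    list(summary = result$summary, markers = result$table),
    json, auto_unbox = TRUE, digits = NA
  )
  invisible(c(tsv, json))
}

#' Simulate a synthetic population and write it as FASTA
#'
#' With `preset = "tenregion"` this reproduces the ten-region study
#' design: `n_seqs` sequences of `seq_len` bp with ten 800 bp marker
#' regions of increasing diversity (see [ten_region_design()]).
#'
#' @param path output FASTA path.
#' @param seed integer RNG seed.
#' @param n_seqs,seq_len population dimensions.
#' @param specs list of `hp_marker_spec`; ignored when `preset` is given.
#' @param preset `"tenregion"` or `NULL`.
#' @return the `hp_population` object, invisibly.
#' @export
run_simulate <- function(path, seed, n_seqs = 10000L, seq_len = 16000L,
                         specs = NULL, preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, "tenregion")
    specs <- ten_region_design(seq_len)
  }
  if (is.null(specs)) stop("either specs or preset must be given",
                           call. = FALSE)
  pop <- make_population_labels(n_seqs, seq_len, specs, seed = seed)
  write_population_fasta(pop, path)
  invisible(pop)
}

#' Run the sample-size experiment and write its TSV report
#'
#' Wraps [sampling_experiment()] with the default configuration (sizes
#' 10/50/100 at 100 replicates, size 1000 at 50 replicates) on a
#' population built from the ten-region design or from supplied specs.
#'
#' @param out_path output TSV path (or `NULL` to skip writing).
#' @param seed integer RNG seed (population and sampling).
#' @param n_seqs,seq_len population dimensions.
#' @param specs,preset population design, as in [run_simulate()].
#' @param sizes,reps experiment configuration.
#' @return the `hp_experiment` data.frame, invisibly.
#' @export
run_sample_size_experiment <- function(out_path, seed, n_seqs = 10000L,
                                       seq_len = 16000L, specs = NULL,
                                       preset = "tenregion",
                                       sizes = c(10L, 50L, 100L, 1000L),
                                       reps = c(100L, 100L, 100L, 50L)) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, "tenregion")
    specs <- ten_region_design(seq_len)
  }
  if (is.null(specs)) stop("either specs or preset must be given",
                           call. = FALSE)
  pop <- make_population_labels(n_seqs, seq_len, specs, seed = seed)
  exp <- sampling_experiment(pop, sizes = sizes, reps = reps,
                             seed = seed + 1L)
  if (!is.null(out_path)) write_experiment_tsv(exp, out_path)
  invisible(exp)
}
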