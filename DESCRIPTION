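Package: haplopanel
Title: Marker Panel Selection Maximizing Haplotypic Diversity of Linked Markers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Selects the subset of linked genetic markers (for example
    mitochondrial DNA SNPs or short windows) that maximizes the haplotypic
    diversity, also known as exclusion capacity, of a sample given as a
    multiple sequence alignment. Polymorphic alignment columns are encoded
    as integer haplotype label vectors (haplocodes); diversity is carried as
    an exact integer separation index equivalent to Nei's estimator;
    redundant and informationally subsumed markers are removed; and the
    optimal marker set of a requested size is found by depth-first
    branch-and-bound search with an exact upper bound and an optional
    heuristic bound controlled by a parameter alpha. Includes a synthetic
    population generator calibrated to prescribed population diversities
    for studying how sample size affects the quality of diversity
    estimates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
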