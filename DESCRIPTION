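Package: p53re
Title: p53 Response Element Scanning and Cross-Species Promoter Conservation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects p53 response elements in promoter sequences by degenerate
    matching of the palindromic RRRCWWGYYY half-site consensus, pairing
    half-sites across 0-13 bp spacers under configurable mismatch budgets.
    Projects reference sites into orthologous promoters via global alignment
    to score cross-species conservation, classifies species by binding-site
    presence/absence with UPGMA dendrograms in Newick format, designs
    site-swap promoter constructs, summarises read-depth-normalised ChIP-seq
    coverage over promoter windows, and ships a seeded synthetic-data
    generator that emits promoters, orthologue cohorts and coverage tracks
    with exact ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    ape,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
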