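Package: zonescan
Title: Fast Protein Similarity Search with Diversified k-Tuple Seeds and
    Diagonal Similarity Zones
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A BLAST-like protein similarity search engine that trades a
    controlled amount of sensitivity for speed. Query sequences are indexed
    in a direct-addressed lookup table of diversified k-tuples (all words
    scoring at least a fraction of the original word's self-match score
    under a substitution matrix). Subject sequences are streamed; word hits
    are aggregated on the fly into diagonal 'similarity zones' which grow,
    merge laterally across adjacent diagonals, and are clustered by single
    linkage before banded Smith-Waterman alignment with affine gaps.
    Alignments are filtered (score, long-repeat), optionally chained into
    super-alignments, ranked by Karlin-Altschul E-values and reported in
    BLAST-like tabular (m8/m9) or text formats. Includes seeded synthetic
    proteome generators for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
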