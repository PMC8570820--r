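Package: pzsearch
Title: Query-Indexed Seed-and-Extend Protein Similarity Search for
    Sample-Annotated Metagenome References
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fast local alignment of protein queries against large,
    sample-annotated metagenomic protein collections.  Builds a k-mer seed
    index over the (small) query set and streams the (large) reference past
    it, extends seeds into gapped high-scoring segment pairs with BLAST-style
    X-drop heuristics, and reports BLAST tabular hits with Karlin-Altschul
    E-values.  Includes a rigorous Smith-Waterman oracle for ground-truth
    benchmarking with precision/recall reporting, hit summarization by
    environment-ontology class, body-site class and geography, and a
    deterministic synthetic-reference simulator with planted homologs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    parallel,
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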