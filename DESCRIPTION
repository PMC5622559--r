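Package: starlign
Title: Center-Star Multiple Sequence Alignment, Keyword-Tree Acceleration
    and Divide-and-Conquer Neighbor-Joining Trees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Desk-scale toolkit for center-star multiple sequence alignment
    (MSA) and distance-based phylogenetics. Proteins are aligned with a
    Smith-Waterman local aligner extended to full-length pairwise alignments
    against a chosen center sequence; highly similar nucleotide sequences are
    aligned with a keyword-tree (failure-link) segment index that restricts
    dynamic programming to unmatched regions. Per-sequence gap records merge
    into a master gap profile via an associative reduce, so alignments are
    independent of partitioning and worker count under the bundled
    map/reduce executor. Phylogenies are built by sampling-based clustering
    of alignment rows, per-cluster neighbor joining, and grafting of cluster
    subtrees onto a backbone tree. Alignment quality is measured with
    sum-of-pairs (SPS) and column (CS) scores against annotated reference
    alignments. A synthetic-data module generates DNA and protein families
    with known ground-truth alignments and edit scripts for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    optparse,
    parallel,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr,
    jsonlite
Config/testthat/edition: 3
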