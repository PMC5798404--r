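Package: plastconcord
Title: Partitioned Plastome Phylogenomics: Selection Scanning, Tree Support and Cross-Partition Concordance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for partitioned plastome phylogenomic analysis. Builds the
    fourteen classic supermatrix partitions (three-gene, all-coding, noncoding
    and complete plastome, each with or without gapped columns and positively
    selected codons), scans protein-coding loci for purifying and positive
    selection with Nei-Gojobori dN/dS counting, a codon-based Z-test and a
    SLAC-style per-site scan, infers bootstrapped neighbor-joining trees or
    imports externally inferred trees, and quantifies clade support,
    concordance and conflict across the resulting trees. A plastome simulator
    with full ground truth (known tree, annotations, selected codons and gap
    columns) makes every stage testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    IRanges,
    jsonlite,
    stats,
    utils
Suggests:
    seqinr,
    phangorn,
    withr,
    optparse,
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
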