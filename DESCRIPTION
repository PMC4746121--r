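Package: gvannot
Title: Annotation and Comparative Analysis of Circular Granulovirus Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for characterising circular double-stranded
    DNA betabaculovirus (granulovirus) genomes: de novo ORF calling on the
    circle under ATG/150-nt/minimal-overlap criteria with granulin-anchored
    numbering, GC content and GC-skew profiling, IUPAC promoter-motif
    scanning of ORF upstream windows, tandem-repeat detection with
    fractional copy numbers, imperfect-palindrome detection and clustering
    into homologous regions (hrs), protein-level features (molecular
    weight, six-cysteine chitin-binding motif, homopolymer runs), pairwise
    gene-order synteny and inversion detection, core-gene auditing, and
    concatenated-marker distance phylogenies (neighbor joining and UPGMA
    with bootstrap). Ships a synthetic-genome generator with full truth
    tables so every stage is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    ape,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    phangorn,
    seqinr
Config/testthat/edition: 3
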