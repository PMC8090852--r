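Package: teclone
Title: Somatic Transposable-Element Insertion Calling from Short and Long Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects non-reference, somatic transposable-element (TE)
    insertions from paired-end short-read and single-molecule long-read
    alignments. Short-read evidence (soft-clipped reads and discordant
    mates with homology to a TE consensus library) is tagged, clustered
    per locus, validated by target-site duplication (TSD) inference and
    filtered against a panel of normals to obtain somatic calls; long
    reads are screened for insertions fully contained in a single read
    and reduced to tissue-specific singletons after read-size
    normalization across libraries. Downstream statistics cover allele
    frequency and cell-fraction timing relative to a clonal expansion,
    per-family TSD summaries, integration-site flank extraction, genic
    annotation and interval-track enrichment tests. A built-in simulator
    implants TE copies with TSDs into clonal cell mixtures and emits
    reads plus gold alignments and a truth manifest, so the whole
    pipeline is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
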