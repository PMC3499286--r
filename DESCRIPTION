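Package: capmap
Title: Full-Length cDNA and EST Pipeline for Draft-Genome Annotation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing full-length-enriched cDNA libraries against a
    draft genome assembly: quality filtering and greedy clustering of 5'-end
    expressed sequence tags (ESTs), selection of clones for full-insert
    sequencing, strand-aware assignment of transcripts to genomic loci by
    anchor-extend-merge of tabular alignments, gene / homolog-group / Gene
    Ontology roll-ups, full-length CDS and open-reading-frame classification,
    locus duplication screening, and estimation of A-to-I RNA editing from
    flank-validated cDNA/genome base discordances. A seeded synthetic-data
    generator emulates full-length-biased cDNA libraries (5'-truncation,
    polymorphism, sequencing error, A-to-G editing at known sites) with a
    ground-truth ledger, so every pipeline stage is testable without external
    downloads. Report builders reproduce the accounting identities of
    library-level EST/clone resource tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    methods,
    rtracklayer,
    stats,
    utils
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
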