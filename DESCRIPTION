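Package: stacer
Title: Tag-Based Discovery of Novel Genes and Reconstruction of
    Full-Length cDNA Ends (STACE)
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computational support for sequence tag-based amplification of
    cDNA ends (STACE): screens SAGE tag libraries against an annotated
    genome to nominate tags that suggest unannotated genes, derives
    gene-specific PCR primers from qualifying tags by reverse complement
    and end trimming with GC/Tm/secondary-structure screens, classifies
    spliced amplicon alignments into novel gene, annotation extension, or
    non-protein-coding overlap calls, validates GT-AG splice signals and
    SL1/polyA full-length evidence, and assembles upstream/downstream
    amplicon pairs into full-length cDNA models. Includes a deterministic
    synthetic-data generator (toy genomes, annotations, tag libraries,
    amplicons) with complete ground truth for offline validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
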