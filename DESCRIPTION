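Package: slimcore
Title: Mapping Short-Linear-Motif Corepressor Interactions from Structure
    Ensembles, Proteomes and Functional Genomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for dissecting transcription-factor to
    corepressor interactions mediated by short linear motifs (SLiMs) such
    as the PLDLS docking motif recognized by CTBP corepressors. Provides
    ensemble interface-frequency scoring on predicted multimer structures
    (Shrake-Rupley solvent accessibility, buried-surface and contact
    interface calls, hydrogen-bond detection, consensus segments),
    proteome-wide motif scanning with anchored flanking-context extraction,
    amino-acid-class context clustering and repeat competitor-construct
    design, protein-complex co-membership network construction with
    community detection, label-free IP-MS differential enrichment with
    permutation FDR, and peak-anchored ChIP-seq signal correlation.
    Seeded synthetic-data generators with machine-readable ground truth
    make every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    ape,
    bio3d,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    seqinr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
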