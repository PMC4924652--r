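Package: mtssr
Title: Nucleosome Distribution Analysis at Transcription Start Sites from
    MNase Fragment Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Downstream analysis of targeted MNase-seq experiments that
    capture the ~2 kb surrounding transcription start sites (mTSS-seq).
    Ingests paired-end mononucleosomal fragment intervals, builds
    fragments-per-million occupancy and windowed dyad (fragment midpoint)
    tracks, detects tumor-versus-normal nucleosome redistribution by
    per-gene correlation change calling and difference-region thresholding,
    clusters promoter nucleosome architectures by k-means, quantifies
    agreement of measured profiles with a DNA-encoded nucleosome occupancy
    model, scores A/T dinucleotide periodicity of protected fragments, and
    measures transcription-factor footprints from sub-nucleosomal
    fragments. A fully seeded synthetic-study generator plants recoverable
    structure (architecture classes, nucleosome-depleted regions,
    condition-specific redistribution, TF footprints, sequence periodicity)
    so that every stage is verifiable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    Rsamtools,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse
Config/testthat/edition: 3
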