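Package: trzsurvey
Title: Motif-Based Survey of Green Plant tRNase Z Proteins and the
    Chloroplast tRNA CCA Census
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for surveying the tRNase Z (RNase Z / ELAC2 homolog)
    protein family in green plants. Compiles degenerate consensus motifs of
    the metallo-beta-lactamase domain grammar (the HxHxDH His motif, the
    flexible-arm KL and GP motifs, PxKxRN/EGxSxxG, HEAT/xExT and HST/HxH),
    scans protein sequences for mismatch-tolerant hits, assembles
    order-consistent motif chains, and classifies candidates into TM-type
    and bacterial-type short forms, the eukaryotic long form, or
    tRNase Z-like proteins (TLPs) lacking required motifs. Also provides a
    census of the trinucleotide immediately downstream of the discriminator
    in chloroplast tRNA genes (CCA/CCN/CNN categories), pairwise
    global-alignment identity and similarity, sequence-logo frequency and
    information-content matrices, neighbor-joining clade checks, and seeded
    synthetic-data generators with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    GenomicRanges,
    IRanges,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
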