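Package: sexbias3d
Title: Sex-Differential CTCF/Cohesin Binding, Intra-TAD Loop Prediction
    and 4C-seq Interaction Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how 3D genome organization shapes
    sex-biased gene expression in mouse liver. Implements windowed
    negative-binomial detection of sex-differential CTCF and cohesin
    (Rad21) ChIP-seq binding with RIPM/FRiP normalization and an
    MA-rescaling lenient tier; replicate-overlap classification of sites
    into CAC, CNC and Lone-CTCF classes with proximity annotation to
    sex-biased genes, enhancers, TADs and intra-TAD loops; prediction of
    intra-TAD loops from convergently oriented CTCF motifs at CAC
    anchors; a 4C-seq pipeline from demultiplexing through
    reduced-genome iterative mapping, median smoothing, RPM
    normalization and distance-decay interaction calling; and
    quantification of cohesin-depletion effects on distally versus
    proximally regulated genes. A synthetic-data generator with known
    planted truth provides closed-loop tests for every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    S4Vectors,
    IRanges,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    edgeR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
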