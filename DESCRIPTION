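Package: defensomics
Title: Defensome Analysis of Annotated (Meta)Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to characterize the anti-phage defense gene repertoire
    (the "defensome") of annotated genomes and metagenome-assembled genomes
    (MAGs). Assembles defense systems from DefenseFinder-style gene hits
    under configurable per-family rules, gates MAGs by MIMAG quality and
    assembly contiguity (N50), computes abundance/density/prevalence
    statistics and their covariation with genome size and phylogenetic
    depth, calls defense islands from gene order, quantifies colocalization
    of defense genes with mobile genetic elements and with each other
    (observed/expected ratios, odds ratios), summarizes high-frequency
    sequence variants per defense family, and estimates pairwise dN/dS by
    the Nei-Gojobori (1986) method. A synthetic-data generator with ground
    truth manifests makes every stage testable without external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    grDevices,
    IRanges,
    jsonlite,
    rtracklayer,
    S4Vectors,
    stats,
    utils,
    vcfR
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
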