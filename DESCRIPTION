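Package: msdintools
Title: Genome-Guided Discovery of MSDIN Cyclic Peptides
Version: 0.1.0
Authors@R:
    person("MSDIN", "Tools Developers", email = "msdintools@example.org",
           role = c("aut", "cre"))
Description: Mining, mass prediction and mass-spectrometric annotation of
    MSDIN-family cyclic peptides from lethal Amanita mushrooms. Detects
    tripartite precursor peptides (10-aa leader, 5-12-aa core, 15-17-aa
    follower) in protein or six-frame-translated nucleotide sequences,
    predicts monoisotopic masses and molecular formulas of the head-to-tail
    macrocyclized cores (including the amatoxin modification state that
    yields alpha- and beta-amanitin), enumerates theoretical MS/MS fragment
    ions (immonium, b/y-type arcs of ring-opened macrocycles, neutral-loss
    variants), matches candidates against MGF peak lists within ppm
    tolerances, and classifies precursor gene expression (FPKM) into tiers.
    Ships a deterministic synthetic-data generator (decoy proteomes,
    contigs, spectra, FPKM tables) for end-to-end testing without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
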