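Package: eggspot
Title: Comparative Expression Evolution of Cichlid Anal-Fin Pigmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for comparative transcriptomics of cichlid
    anal-fin pigmentation ornaments (egg-spots and blotches). Implements
    BLAST-hit filtering with all-species presence selection, plurality
    consensus building and reading-frame validation for ortholog sets;
    pairwise dN/dS estimation by the Nei-Gojobori (1986) counting method
    with per-gene averaging and gene-set rate comparison; comparative
    threshold-cycle (delta-delta-CT) qPCR quantification with a
    normality/variance-gated statistical test cascade producing discrete
    expression calls; and expression-character clustering via mean
    character difference distances, neighbor joining and character
    bootstrap. Includes seeded synthetic-data generators (codon-pair
    evolution under a target dN/dS, CT tables, discrete call matrices,
    BLAST hit tables) so every stage is testable with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    ape,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
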