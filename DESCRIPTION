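Package: aquamip
Title: Genome-Wide Characterization of Plant Aquaporin (MIP) Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis toolkit for genome-wide censuses of plant major
    intrinsic proteins (aquaporins). Curates MIP candidate sequences by the
    dual-NPA criterion, classifies PIP/TIP/NIP/SIP/XIP subfamilies against a
    labelled reference panel, transfers the selectivity-determining residues
    (NPA motifs, ar/R filter, Froger positions) from an annotated template by
    pairwise global alignment, predicts transported substrates with an
    auditable residue-signature rule base, computes protein physico-chemical
    properties (isoelectric point, molecular weight), builds
    Poisson-corrected neighbour-joining phylogenies with bootstrap support,
    screens qPCR primers with nearest-neighbour DNA thermodynamics, and
    quantifies relative expression (geNorm reference stability, dilution-curve
    efficiency, 2^-ddCt, tier grouping, cross-platform concordance). Includes
    deterministic synthetic-data generators so every stage is testable
    without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
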