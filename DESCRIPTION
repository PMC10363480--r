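Package: chimeraTP
Title: Converting Antimicrobial Peptides into Organelle-Targeting Peptides
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
        role = c("aut", "cre"))
Description: Sequence-level toolkit for studying how cationic amphipathic
    antimicrobial peptides (HA-RAMPs) relate to mitochondrial presequences
    (mTPs) and chloroplast transit peptides (cTPs). Implements amphipathic
    alpha-helix detection on the helical-wheel principle with per-residue
    hydrophobic moments, Z-scale auto-cross-covariance (ACC) featurization
    (36 terms), Boman index, charge profiles and amino-acid frequency
    tables, window-rule motif scanning (FGLK TOC-interaction sites, Hsp70
    binding, N-terminal multi-R), a chimeric construct grammar for fusing
    targeting-peptide elements (cTP-N, cTP-C, mTP-C) onto peptide cores
    with K/R substitution, a balanced resampled cross-validated penalized
    logistic-regression protocol for mTP/cTP discrimination, bookkeeping
    and tallies for construct-targeting outcome grids, seeded synthetic
    peptide generators emulating mTP-like, cTP-like and HA-RAMP-like
    statistical structure, and the associated group-comparison statistics
    (Welch t-tests, Kruskal-Wallis with Dunn post hoc tests).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'peptide-core.R'
    'physchem.R'
    'classify.R'
    'grid.R'
    'helix-finder.R'
    'motifs.R'
    'stats-report.R'
    'synthetic.R'
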