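Package: xlmod
Title: Crosslink-Guided Structural Modelling and Size Analysis of Protein Oligomers
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An integrative toolkit for structural analysis of oligomeric
    proteins by chemical crosslinking mass spectrometry (XL-MS), elastic
    network normal-mode analysis and small-angle X-ray scattering (SAXS).
    Provides monoisotopic mass arithmetic for crosslinked peptides with
    14N/15N metabolic labelling, in-silico trypsin/chymotrypsin digestion and
    a minimal crosslink spectrum search with mixed-isotope subunit-exchange
    detection, mapping of lysine-lysine crosslinks onto candidate structural
    models with distance-based classification and best-fit model selection,
    export of docking restraints, anisotropic-network normal mode analysis
    for per-residue flexibility profiling, and SAXS Guinier/Kratky/Porod and
    P(r) analysis with oligomer mass and subunit-count estimation. A seeded
    synthetic-data module generates toy structures, decoy ensembles,
    crosslink spectra and scattering curves so every stage can be exercised
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
biocViews: MassSpectrometry, Proteomics, StructuralPrediction, Software
RoxygenNote: 7.3.3
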