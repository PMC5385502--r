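Package: hydrin
Title: Hydrophobin Sequence Space, Structure Metrics and Rodlet Morphometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for fungal hydrophobins. Mines protein
    sequences for the canonical eight-cysteine arrangement (C, CC, C, C, CC,
    C), extracts inter-cysteine spacing features and canonical disulfide
    connectivity, performs principal component analysis of multiple sequence
    alignment similarity matrices to resolve Class I/II structure in sequence
    space, partitions the component plane into regions with per-region
    consensus sequences and composition summaries, computes structure-derived
    metrics from PDB coordinates (Shrake-Rupley solvent accessible surface
    area and hydrophobic fraction, disulfide detection, Kabsch superposition
    RMSD, molecular weight, principal-axis bounding dimensions, buried
    hydrophobic interface area), and reproduces an AFM rodlet morphometry
    chain (unsharp mask, despeckle, threshold, ellipse-fit particle analysis).
    Includes generators for class-structured synthetic sequences, toy
    structures and simulated height images so every stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    bio3d,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    seqinr
Config/testthat/edition: 3
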