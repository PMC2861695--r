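Package: polyqdmd
Title: Discrete Molecular Dynamics Pipeline for Polyglutamine and
    Huntingtin Exon1 Misfolding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Event-driven discrete molecular dynamics (DMD) over square-well
    potentials with replica exchange, and a downstream analysis pipeline for
    studying the misfolding of polyglutamine peptides and huntingtin exon1
    constructs: weighted histogram analysis (WHAM) of multi-temperature energy
    samples into a density of states and heat-capacity curves, screening of
    compact low-energy conformations by radius-of-gyration and energy cutoffs,
    per-residue secondary-structure probabilities from backbone dihedral
    angles, and single-linkage clustering of conformations on pairwise RMSD
    with centroid extraction. Includes deterministic synthetic-data generators
    (ideal backbones, two-state energy series, Boltzmann replica samples,
    structure blobs) so every stage can be validated against known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    mclust,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    Biostrings,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
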