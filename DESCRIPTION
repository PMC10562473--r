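Package: phosphosep
Title: Multisite Phosphorylation and Phase Separation of Disordered Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Sequence-based analysis of how CDK multisite phosphorylation
    switches the phase-separation propensity of intrinsically disordered
    proteins. Provides charge-sequence models with phosphorylation and
    phosphomimetic editing, sequence charge decoration matrices (SCDM),
    random-phase-approximation phase diagrams with exhaustive
    phosphosite-combination scans, pLDDT- and IUPred-based selection of
    disordered regions, a coarse-grained one-bead-per-residue Langevin
    simulator with theta-temperature and binodal fitting, FRAP recovery
    kinetics fitting, and compositional-bias-corrected enrichment statistics
    of phosphorylation in disordered regions, together with seeded synthetic
    data generators so the whole pipeline runs end-to-end offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    bio3d,
    minpack.lm,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
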