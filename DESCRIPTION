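Package: cprfit
Title: Induced-Fit, Interface and Regiospecificity Analysis for
    Cytochrome P450 Reductase-CYP Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Structural and biochemical analysis of complexes between the
    FMN-binding domain (FD) of cytochrome P450 oxidoreductase (CPR) and
    cytochrome P450 1A2. Implements a per-residue induced-fit statistic
    (complexed-versus-free side-chain RMSD over relaxation ensembles,
    corrected by an intradomain relaxation baseline), consensus
    interface-contact mapping across docked pose ensembles, flavin/heme
    cofactor geometry checks, bound-minus-free RMSF-difference trajectory
    analysis, and the data reductions for caffeine regiospecificity assays
    of CPR-variant membrane fractions (metabolite profiles, mass balance,
    CPR:CYP stoichiometry, stability and rate conversions). Ships
    synthetic-structure, trajectory and assay-table generators so the whole
    pipeline is testable without external modelling software.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
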