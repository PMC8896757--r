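Package: thermoenv
Title: Thermodynamic Environment Profiling of Proteins and Proteomes
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Coarse-grains per-residue thermodynamic descriptors (local
    stability, apolar and polar enthalpy, conformational entropy) into an
    eight-letter alphabet of native and denatured thermodynamic environments
    (TEs) by weighted Manhattan distance to published cluster centers.
    Profiles proteomes by TE usage frequency with UPGMA clustering, principal
    component analysis and organism-trait regressions; scores secondary
    structure enrichment per TE by log-odds; and fits an additive TE-based
    model of global protein stability with leave-one-out bootstrapping, which
    also discriminates structured from intrinsically disordered proteins. A
    fully seeded synthetic-data generator emulates every upstream input with
    known ground truth so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    cluster,
    optparse
biocViews: Proteomics, Clustering, PrincipalComponent, StructuralPrediction
Config/testthat/edition: 3
RoxygenNote: 7.3.3
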