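Package: polyqdmd
Title: Discrete Molecular Dynamics and Aggregation Analysis for PolyQ Exon-1 Oligomers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Event-driven discrete molecular dynamics (DMD) for coarse-grained
    huntingtin exon-1-like constructs with expandable polyglutamine tracts,
    together with the analysis stack used to characterize hetero-oligomerization:
    temperature replica exchange with Metropolis swaps, per-residue beta-structure
    probability profiles with binomial error bars, mean smallest-distance and
    cross-beta contact maps, aggregate-precursor detection (beta sheets spanning
    two chains), single-linkage conformational clustering with medoid extraction,
    and Monte-Carlo simulated-annealing ddG point-mutation scanning on oligomer
    structures. Includes synthetic-trajectory generators with planted ground
    truth so every analysis stage is testable without engine runs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
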