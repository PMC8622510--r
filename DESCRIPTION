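Package: fieldqsar
Title: Grid-Based 3D-QSAR Modelling and End-State Binding Free Energy
    Aggregation for Kinase Inhibitor Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ligand-based three-dimensional quantitative structure-activity
    relationship (3D-QSAR) modelling for aligned small-molecule series, with
    an emphasis on FLT3 kinase inhibitor analysis. Computes comparative
    molecular field analysis (CoMFA) steric and electrostatic probe fields
    and comparative molecular similarity index analysis (CoMSIA) Gaussian
    property fields on a rectangular lattice, fits partial least squares
    (PLS) regression models with leave-one-out cross-validation and optimal
    component selection, and provides the full internal/external validation
    battery (chi-squared and RMSE fitness, Golbraikh-Tropsha through-origin
    criteria, the rm2 metric family, QF3^2, Lin's concordance correlation),
    progressive scrambling stability analysis, leverage-based applicability
    domain (Williams plot) classification, and StDev*Coeff contour field
    export. A companion layer aggregates per-frame molecular mechanics
    Poisson-Boltzmann/generalized Born surface area (MM-PB(GB)SA) energy
    components into binding free energy breakdowns, computes linear
    interaction energy (LIE) estimates, and processes per-residue energy
    decomposition tables. A seeded synthetic-data generator produces aligned
    analog series, planted linear field-activity relationships, and
    stationary energy-component time series so that every stage of the
    pipeline is testable without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    withr,
    ChemmineR,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    optparse,
    mixOmics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
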