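Package: aggtraj
Title: Aggregate Tracking and Membrane-Relative Metrics for Molecular
    Co-Assembly Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies peptide-drug co-assembly in molecular dynamics
    trajectories. Identifies aggregates per frame by density-based
    clustering (DBSCAN) of molecular centers of mass under periodic
    boundary conditions, backtracks a focal aggregate through time by
    maximal membership overlap to record growth and shrink events, and
    computes membrane-relative observables: bilayer surface distance from
    leaflet phosphorus centers of mass, lipid contact counts, complex
    ratio, average aggregation number, and aggregate composition tables.
    Includes a deterministic synthetic-trajectory generator with planted
    ground truth (scripted fusion, fission and membrane-binding events,
    optional slab bilayer) so the whole pipeline is testable without
    simulation output, plus readers for GRO and PDB files and a native
    plain-text fixture format.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    ggplot2,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
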