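Package: porekin
Title: Water-Channel Geometry, Proton-Pathway Energetics, and
    Conformational Kinetics from Molecular Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Trajectory-analysis toolkit for pH-gated water and proton
    channels in membrane light-harvesting proteins.  Provides pore-radius
    profiling along the membrane normal by sphere maximization, water
    radial distribution functions, dipole orientational order profiles,
    continuous (switching-function) coordination numbers, directed
    water-current estimation from forced trajectories, time-averaged
    density grids with immobile-water site detection, two-dimensional
    free-energy surfaces with Dijkstra minimum-energy paths,
    transition-charge (TrESP) excitonic couplings with
    protonation-state switching, and a from-scratch conformational
    kinetics stage (torsion featurization, tICA, k-means microstates,
    Markov state models, implied timescales, Chapman-Kolmogorov
    validation, PCCA+ macrostates, and reweighted free-energy surfaces).
    Seeded synthetic-data generators with known ground truth support
    end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
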