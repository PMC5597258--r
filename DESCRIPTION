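Package: caspatial
Title: Stochastic Spatio-Temporal Calcium Cycling in Cardiac Myocytes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates three-dimensional stochastic intracellular calcium
    cycling in ventricular cardiomyocytes on voxel geometries derived from
    (or emulating) electron-microscopy reconstructions of the transverse
    tubules and sarcoplasmic reticulum. The sarcoplasmic reticulum is
    reduced to a three-dimensional network of one-dimensional strands by
    medial-axis thinning; dyads couple stochastic Markov-chain ryanodine
    receptor and L-type channel clusters to a restricted subspace, the
    cytoplasm and the network store; membrane fluxes are distributed on
    sarcolemma and t-tubule maps and coupled to a reduced human-ventricle
    derived action-potential model. Includes protocol drivers for paced
    beats, calcium-transient alternans, spark hierarchy, two-dyad spark
    propagation and overload-induced spontaneous release, plus an analysis
    layer for transient metrics, phase maps, release-event detection and
    linescans.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
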