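Package: nanotrap
Title: Spatiotemporal Nanocluster Detection, Lateral Trapping Analysis and
    Reaction-Diffusion Modelling of Membrane Recruitment
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing single-particle tracking (sptPALM) data of
    membrane proteins that are recruited to the plasma membrane and trapped in
    endocytic nanoclusters. Provides a ground-truth synthetic trajectory
    generator, TRXYT/CSV trajectory input and output, MSD-based mobility
    metrics, spatiotemporal (3D) DBSCAN nanocluster detection with cluster
    metrics and hotspot analysis, a lateral-trapping trajectory filter with
    entry-aligned displacement statistics, fluorescence recruitment-kinetics
    quantification, and a six-species membrane reaction-diffusion model of
    dynamin cluster growth with deterministic, stochastic and reduced spatial
    simulators plus genetic-algorithm parameter fitting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    deSolve,
    Matrix,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
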