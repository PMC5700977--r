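Package: ccdyn
Title: Consensus Connectome Dynamics and Doubly-Preferential Attachment
    Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying Consensus Connectome Dynamics (CCD) in
    ensembles of structural braingraphs: k-consensus connectome
    construction from per-edge subject frequencies, CCD trajectories and
    isolated-edge counts, a quarter-set Monte-Carlo discordance statistic
    for the robustness of edge and vertex appearance orders, and a
    doubly-preferential attachment random-graph simulator with
    exponential-growth fitting and isolated-edge calibration. Includes a
    synthetic ensemble generator with a planted developmental order so the
    whole pipeline is testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    minpack.lm
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
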