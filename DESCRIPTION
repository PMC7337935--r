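Package: oxtraj
Title: Trajectory Analysis and Rigid-Body Relaxation for Coarse-Grained
    Nucleic-Acid Simulations
Version: 0.1.0
Authors@R:
    person("oxtraj", "developers", email = "oxtraj@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing oxDNA-style coarse-grained DNA/RNA
    nanostructure simulations: readers and writers for topology,
    configuration and trajectory files, SVD-based superposition with mean
    structures and per-nucleotide RMSF, mean structures from local contact
    maps via multidimensional scaling, duplex detection with axis fitting
    and interduplex angle statistics, hydrogen-bond occupancy against a
    designed pair list, principal component analysis of motion modes,
    DBSCAN clustering of sampled conformations, and a rigid-body
    relaxation engine for arranging exported designs into
    simulation-ready starting states. Includes a synthetic structure and
    trajectory generator with known ground truth, viewer-compatible JSON
    data overlays, and a command-line interface with chunked
    parallelisation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    parallel,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
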