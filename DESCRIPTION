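Package: chitofib
Title: Chitosan Nanofibril Construction and Trajectory Analysis
Version: 0.1.0
Authors@R:
    person("Fibril", "Analytics", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds crystallographic models of chitosan nanofibrils
    (P2(1)2(1)2(1) symmetry expansion, sheet/chain/residue topology) and
    analyses molecular-dynamics trajectories of them: geometric hydrogen-bond
    detection with topological classification (intra-chain, intra-sheet,
    inter-sheet, chitosan-water), per-pair occupancies, hydration observables
    (bound/bulk/interior water, water-bridged hydrogen bonds), structural
    observables (convex-hull volume and volume change, end-to-end distance,
    RMSF, sheet-stacking distance), and dipole-orientation statistics under an
    external field reference. Includes a synthetic-trajectory generator with
    planted ground truth for estimator validation, plain-text PDB/mmCIF/DCD
    readers and writers, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    grDevices,
    graphics,
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
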