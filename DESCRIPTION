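Package: ligpath
Title: Ligand Binding Pathway Analysis for Molecular Dynamics Trajectories
Version: 0.1.0
Authors@R:
    person("ligpath", "developers", email = "ligpath@example.org",
           role = c("aut", "cre"))
Description: Detects agonist association and docking events in molecular
    dynamics trajectories of ligand-binding domains, splits binding chains
    into binding and unbinding pathways, clusters pathways by the weighted
    average Hausdorff distance with Ward linkage, profiles guiding residues
    by fractional occurrence and the overlap (Szymkiewicz-Simpson)
    coefficient, estimates association rate constants from bulk residence
    accounting, and computes order-parameter free-energy surfaces by direct
    histogramming and two-dimensional WHAM with block-averaged errors.
    Ships synthetic-trajectory and umbrella-sample generators with ground
    truth so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
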