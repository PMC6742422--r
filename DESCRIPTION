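Package: tubemech
Title: Mechanics of Tubulin Interfaces from Structures and Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis of the mechanics of intra- and inter-dimer tubulin
    interfaces in microtubule protofilaments. Decomposes the relative
    orientation of adjacent tubulin monomers into bend magnitude, bend
    direction and twist angles in a microtubule-bound coordinate frame;
    estimates harmonic angular stiffness from equilibrium fluctuations via
    the equipartition theorem; performs essential-dynamics PCA of
    coordinate trajectories; builds and parametrizes heterogeneous elastic
    network models, computes normal modes and converts mode frequencies to
    beam-theory bending and torsional rigidities; and quantifies interface
    contacts and nucleotide-based compaction. A synthetic-trajectory
    generator provides ground-truth inputs for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
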