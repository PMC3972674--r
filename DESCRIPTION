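Package: srbm
Title: Spatial Rule-Based Modeling of Molecular Self-Assembly
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Coarse-grained particle simulator in which molecular complexes
    self-assemble under BNGL-style reaction rules constrained by explicit
    molecular geometry. Molecules are spheres (or multi-sphere structural
    templates) whose radii derive from molecular mass; binding sites are
    placed on the sphere surface in spherical coordinates. Particles move by
    overdamped Brownian dynamics with excluded volume, harmonic bonds,
    reflective boundaries and an optional centering drag, and reaction rules
    fire when reactive sites come within reach. Includes a structural
    analysis toolkit (positional, paired and local RMSD, UPGMA dendrograms,
    bond-frequency and connectivity statistics) and a bundled model of the
    human mitotic kinetochore with its spindle-assembly-checkpoint switch.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    ape,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
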