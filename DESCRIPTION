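Package: helixpack
Title: Ligand-Biased Repacking of Seven-Transmembrane Helix Bundles
Version: 0.1.0
Authors@R: person("helixpack", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Semi-empirical modelling of the membrane-spanning part of
    G-protein coupled receptors by rigid-body repacking of the seven
    transmembrane helices around a bound ligand. Helices are perturbed in an
    internal-coordinate (virtual-variable) representation, re-assembled by a
    four-stage Monte Carlo geometry optimization under conserved-residue
    tethers and flat-bottom ligand anchor restraints, scored with a
    packing/orientation/ligand scheme with two filtering checkpoints, and the
    surviving receptor models are ranked by the number of unique agonists that
    pass hydrogen-bond and aromatic-contact docking-pose criteria. Includes
    deterministic generators for idealized helix bundles, graded decoys and
    toy ligands so the full pipeline runs without external structure files.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
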