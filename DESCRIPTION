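Package: memswarm
Title: Membrane-Driven Rigid-Body Docking of Membrane-Associated Protein
    Complexes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integrative modelling of complexes between a membrane-embedded
    receptor and a soluble partner. A coarse-grained lipid snapshot is reduced
    to its phosphate beads, the bead bilayer restricts pose sampling to the
    membrane-compatible side of the receptor, and ligand poses are optimized
    by glowworm swarm optimization under a distance-binned statistical
    potential that heavily penalizes membrane penetration. Docked models are
    relieved of steric clashes by a restrained minimizer, re-scored with a
    weighted physics-based energy, and evaluated with CAPRI quality metrics
    (Fnat, interface and ligand RMSD, quality classes, success rates).
    Synthetic fixture generators (toy transmembrane complexes, planar bead
    membranes, pseudo coarse-grained snapshots, graded decoys) make the whole
    pipeline runnable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
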