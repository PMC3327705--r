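Package: mifscan
Title: Comparative Molecular Interaction Field Analysis for Protein Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes molecular interaction fields (MIFs) on regular grids
    around charged protein structures and compares them across a protein
    family. Electrostatic potentials come from a finite-difference solution
    of the linearized Poisson-Boltzmann equation; hydrophobic interaction
    fields from a DRY-style probe combining Lennard-Jones attraction, a
    water-entropy reward and a hydrogen-bond competition penalty. Fields are
    compared pairwise with the Hodgkin similarity index over a skin of grid
    points just outside the molecular surface, globally and in spheres
    around each residue, yielding similarity/distance matrices, UPGMA
    "epograms", ordered heatmaps and per-residue conservation profiles.
    Includes a synthetic pseudo-protein cohort generator with known group
    structure for validation, PQR/PDB/OpenDX input-output and an end-to-end
    pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    ape,
    bio3d,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
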