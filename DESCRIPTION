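Package: surfscape
Title: Lipophilic and Electrostatic Surface Potentials for Protein Visualization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Computes the molecular lipophilic potential (MLP, Broto-style
    atomic fragment values under an exponential distance kernel) and a
    screened-Coulomb electrostatic potential (EP) on regular grids around
    protein structures, builds watertight Gaussian molecular-surface triangle
    meshes, maps grid scalars onto mesh vertices by trilinear interpolation
    and derives gray/specular/roughness material channels, traces
    electrostatic field lines from Monte Carlo-selected surface seeds, and
    turns the lines into per-frame particle animation schedules, for still
    structures and multi-model frame sequences. Reads and writes PDB, PQR,
    OpenDX scalar grids, Wavefront OBJ meshes and an ASCII field-line format.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
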