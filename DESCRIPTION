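Package: fsnma
Title: Normal Mode Analysis for Interpreting Single-Molecule Force
    Spectroscopy on Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Elastic-network normal mode analysis (NMA) toolkit for
    interpreting single-molecule optical-trap pulling experiments on
    proteins.  Builds C-alpha elastic network models from PDB structures,
    rotates the tether (pulling) axis onto a coordinate axis, computes
    normal modes together with per-residue square fluctuations,
    mechanical stiffness and mode collectivity, identifies modes that
    separate user-defined domains along the pulling direction, distorts
    the structure along those modes to a target RMSD (single-mode,
    pseudo-trajectory, stochastic ensembles and RMSD ramps), and ranks
    domain structural integrity by the volume of residues remaining in
    the buried core.  Includes parametric synthetic fixtures (dimers,
    helices, two-lobe dumbbells) with analytically known mechanics, and
    a five-step pipeline driver with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    graphics,
    grDevices,
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
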