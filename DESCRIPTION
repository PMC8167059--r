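Package: fdrmap
Title: False Discovery Rate Confidence Maps and Backbone Validation for
    Cryo-EM Atomic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes voxel-wise confidence maps from cryo-EM density
    volumes by estimating the background noise distribution from cubes
    placed outside the particle, converting voxel intensities to
    right-tailed Gaussian p-values, and adjusting them for multiplicity
    with the Benjamini-Yekutieli (or Benjamini-Hochberg) step-up
    procedure. Atomic models in PDB or mmCIF format are scored per
    residue by the confidence that their backbone atoms sit in molecular
    signal rather than background, and low-confidence residues can be
    pruned automatically (together with their flanking neighbours) for
    the next round of iterative model building. Includes a synthetic
    scene generator (Gaussian-atom maps with known ground-truth masks and
    deliberate mistraces) so the whole pipeline is testable without
    experimental data, plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
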