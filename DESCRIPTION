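Package: pocketcons
Title: Conservation-Weighted Consensus Nomination of Ligand-Binding Pockets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Nominates and characterizes ligand-binding pockets on candidate
    receptor proteins by combining multi-detector pocket predictions with
    reference-domain sequence conservation. Implements Needleman-Wunsch global
    alignment with affine gaps and EMBOSS-style free end gaps, per-detector
    z-score consensus ranking of pocket predictions, a Poisson
    conservation-enrichment statistic over pocket-lining atoms, conversion of
    docking binding free energies to inhibition constants, geometric
    hydrogen-bond detection, and molecular-dynamics trajectory metrics (RMSD
    after Kabsch superposition, radius of gyration, per-residue RMSF,
    hydrogen-bond time series and mean smallest-distance residue matrices).
    A synthetic-data generator produces structures, homolog sequence pairs,
    pocket-detector outputs and noisy rigid-body trajectories with known
    ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    optparse
Config/testthat/edition: 3
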