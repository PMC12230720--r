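Package: emapfit
Title: Assembly of Protein-Nucleic Acid Complexes from Cryo-EM Density Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds atomic models of protein-nucleic acid complexes from
    cryo-EM density maps by fitting independently modeled chains. The map is
    first segmented into protein, nucleic-acid and background regions with a
    trainable 3-D encoder-decoder network; each chain is then fitted into its
    segmented region by multi-start rigid-body L-BFGS optimization of a
    composite correlation score, with iterative masking of already-explained
    density, domain-level flexible refinement for protein chains, and a final
    combinatorial pose selection by differential evolution followed by a
    joint rigid-unit refinement. Includes a synthetic-complex generator that
    simulates density maps, ground-truth voxel labels and poses, so the whole
    pipeline is testable without external data, plus scoring utilities
    (global/local/per-residue map correlation, Fourier shell correlation,
    TM-score, RMSD, steric clash score) and MRC2014 map input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
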