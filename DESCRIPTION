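Package: sadef
Title: Structural-Alphabet Analysis of Secondary-Structure Shape and
    Deformation at Protein Interfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Encodes protein C-alpha backbones into a 27-letter structural
    alphabet (four-residue fragments described by three inter-carbon
    distances and an oriented plane projection, decoded with a hidden
    Markov model), classifies residues of two-chain complexes into
    interface, surface and core compartments from relative solvent
    accessibility computed with an internal Shrake-Rupley engine, and
    quantifies letter-compartment preferences (Kullback-Leibler
    divergence with chi-square assessment, Z-scores with Bonferroni
    thresholds, correspondence analysis, descriptor PCA) and
    bound/unbound conformational deformation (transition matrices,
    interface-minus-surface deformation differences, exposure changes,
    Kabsch RMSD). Synthetic-structure generators make the whole pipeline
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
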