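Package: allonet
Title: Coarse-Grained Allostery Analysis of Amino-Acid Binding Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Elastic-network and relational-inference analysis of the
    open-to-closed transition of bacterial periplasmic amino-acid binding
    proteins (GlnBP, HisJ, LAOBP and relatives). Implements Gaussian and
    anisotropic network models on C-alpha structures (fast/slow mode
    fluctuation profiles, cross-correlation maps, hot-spot and hinge
    detection, open-to-closed mode overlap), a desk-scale neural relational
    inference variational autoencoder that learns discrete interaction
    edges from coarse-grained trajectories, shortest-path allosteric
    signalling analysis from substrate-binding residues to the I-Loop,
    per-residue binding-energy table filtering, and a synthetic-data
    generator (two-lobe hinge structures, elastic-network-sampled
    trajectories, interacting spring-particle systems) that supplies every
    input the pipeline needs without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
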