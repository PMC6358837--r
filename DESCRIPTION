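Package: npprofiler
Title: Chemoinformatic Profiling and Diversity Analysis of Compound Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for curating and profiling small-molecule compound
    libraries, with an emphasis on natural-product collections. Reads
    SMILES, SDF and CSV libraries; standardizes structures (salt
    stripping, charge neutralization, canonicalization, duplicate
    removal); computes six physicochemical properties of pharmaceutical
    relevance (MW, SlogP, TPSA, rotatable bonds, H-bond donors and
    acceptors) with box-plot summary statistics; extracts Bemis-Murcko
    molecular frameworks and quantifies scaffold diversity through
    cyclic-system recovery curves and their area under the curve;
    computes 166-bit structural-key fingerprints with Tanimoto
    similarity statistics; embeds libraries in chemical space by PCA of
    scaled properties and t-SNE of fingerprints; and assembles Consensus
    Diversity plots that compare libraries by fingerprint, scaffold and
    property diversity simultaneously. A seeded synthetic-library
    generator with known scaffold multiplicities supports end-to-end
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    Rtsne,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
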