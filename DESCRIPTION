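Package: icebonds
Title: Intrachain Hydrogen Bonds and Salt Bridges in Fish Proteasome Subunits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Geometric detection of intrachain hydrogen bonds and salt
    bridges in single-chain protein structures, with tools for comparing
    interaction networks across orthologous proteins. Includes PDB and
    FASTA input/output, polar-hydrogen inference for heavy-atom models,
    configurable distance and angle criteria, cross-species matching of
    salt-bridge residue pairs into conserved and species-specific sets,
    pairwise ortholog sequence comparison with conservation-class and
    polarity-change annotation, species-level interaction-count profiles
    and stability rankings, and a seeded generator of synthetic
    single-chain structures with ground-truth interaction manifests.
    Motivated by comparative structural stability of the proteasome
    catalytic subunits (beta1, beta2, beta5) of temperate and Antarctic
    fish.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
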