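Package: kcxlink
Title: Cleavable Lysine-Cysteine Cross-Linking Mass Spectrometry Toolkit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Toolkit for cysteine-enabled cleavable cross-linking mass
    spectrometry (XL-MS) with heterobifunctional lysine-cysteine (K-C)
    cross-linkers such as SIA, SIAB and SBAP. Implements the elemental
    composition and monoisotopic fragment-mass model for oxidized K-C
    cross-links and their sulfoxide-driven C-S cleavage products
    (sulfenic-acid, unsaturated-thiol and alkene remnants), MS2 signature-pair
    detection, MS3 and stepped-HCD MS2 cross-link search with target-decoy
    false discovery rate control, aggregation to unique residue-to-residue
    linkages, Calpha-Calpha distance mapping of linkages onto experimental and
    predicted structures with homo-oligomer rescue and AlphaFold
    confidence gating (PAE, pLDDT), secondary-structure enrichment, and
    protein-protein interaction network assembly. Includes a fully seeded
    synthetic-data generator (proteomes, MSn runs, toy structures) so the
    whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    rlang,
    readr,
    jsonlite,
    ggplot2,
    generics,
    stats,
    utils,
    igraph,
    bio3d,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    stringr,
    tidyr,
    mzR,
    optparse,
    withr
Config/testthat/edition: 3
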