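Package: protblocks
Title: Protein Blocks Encoding and Knowledge-Based Local Structure Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Encodes protein backbones into the 16-letter Protein Blocks (PB)
    structural alphabet from phi/psi dihedral angles (nearest-prototype
    assignment under an angular root-mean-square dissimilarity), builds a
    pentapeptide knowledge base mapping amino-acid 5-mers to the central-residue
    PBs they adopt in known structures with sequence-identity tier metadata,
    and predicts PB sequences for query amino-acid sequences by majority-rule
    or context-aware hybrid scoring, with optional homologue-tiered (noise
    filtering) querying. Includes tri-PB/penta-PB motif frequency tables, a
    log-frequency plausibility score that self-estimates prediction accuracy,
    evaluation utilities (Q16, per-PB Matthews correlation, relaxed-equivalence
    accuracy), and a fully synthetic fixture generator (PB strings, backbone
    reconstruction, homologue families) so the whole pipeline runs
    self-contained.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    data.table,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    Biostrings,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
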