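Package: tntsim
Title: In Silico Three-Nucleotide-Signature (TNT) Type IIS Cloning Simulator
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A methylation-aware simulator of type IIS restriction
    digestion and Golden-Gate-style overhang ligation built around the
    TNT (three-nucleotide signature) cloning platform: a registry of the
    17 entry/alpha/omega vector members and their 3-nt signature grammar,
    deterministic and stochastic (partial) digestion with
    methyltransferase-blocked sites, one-pot digestion-ligation product
    enumeration with ORF-continuity checks, a minimal-depth multi-round
    assembly planner with end-to-end sequence-level simulation,
    synonymous-recoding (domestication) of internal recognition sites,
    design of 26-nt site-masking (BlindSpot) oligonucleotides, and
    library-entry primer design with a nearest-neighbour melting
    temperature model.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
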