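Package: acylscan
Title: Motif-Grammar Scanning and Comparative Survey of Glycerolipid
    Acyltransferases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for classifying glycerol-3-phosphate and
    dihydroxyacetone-phosphate acyltransferases (GPAT/DHAPAT, acyltransferase
    domain pfam01553) into six opisthokont subclasses from protein sequence
    alone.  Implements a degenerate motif grammar for the four sequential
    acyltransferase signature motifs, chain placement under inter-motif
    spacing (DBM) constraints, HX4D/HX5D motif-I discrimination, rule-based
    C-terminal PTS1 peroxisomal targeting calls, an iterative homology survey
    with reciprocal-best-hit validation and motif-anchored profile scoring,
    neighbor-joining subfamily clustering with monophyly checks, and a
    synthetic proteome generator so the whole pipeline is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
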