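Package: mirmimic
Title: Design and Analysis of Chemically Modified microRNA Mimics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for encoding, translating and analysing chemically modified
    microRNA mimic duplexes. Represents modified RNA strands (2'-O-methyl,
    2'-fluoro, 2'-deoxy sugars; phosphorothioate linkages) at per-residue
    resolution, ships a declarative registry of mimic modification templates
    together with an engine that applies or translates a template to any miRNA
    sequence, computes elemental composition and neutral mass of modified
    strands, scans 3'UTR sequence sets for exact seed-complementary sites and
    intersects them with differential-expression tables, and implements
    comparative 2^-ddCt qPCR and dual-luciferase percent-activity
    quantification. Deterministic synthetic-fixture generators with planted
    ground truth make every analysis step testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
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
    tidyr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
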