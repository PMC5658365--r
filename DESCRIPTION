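Package: sevaforge
Title: In Silico Golden Gate Assembly and Integrative Vector Design for
    Bacillus SEVA Siblings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the construction of standardized integrative vectors
    for Bacillus subtilis and relatives: type IIS restriction digestion with
    typed sticky ends, one-pot Golden Gate assembly with product enumeration,
    classification and colony-color prediction, a parts/marker registry with
    the SEVA-style three-digit nomenclature codec, homology-arm and primer
    design for arbitrary chromosomal loci, multi-enzyme polylinker (MCS-IIS)
    synthesis, SEVA compliance checking, and linearization followed by
    double-crossover integration into a genome. Ships a deterministic
    synthetic-fixture generator so the whole pipeline is testable offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    jsonlite,
    withr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
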