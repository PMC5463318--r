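Package: ontorec
Title: Multi-Criteria Ontology Recommendation for Biomedical Text
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ranks biomedical ontologies, and sets of ontologies, by how well
    they annotate a free-text passage or a comma-delimited keyword list. A
    dictionary-based concept recognizer matches class preferred names and
    synonyms against the input; candidate ontologies are then scored on four
    criteria (input coverage with overlap resolution and a multi-word bonus,
    community acceptance from repository presence and visit counts, class-level
    detail, and size-penalized specialization) and the criterion scores are
    combined into a weighted relevance score. Includes a legacy single-formula
    scorer for comparison, enumeration and pruning of 2- and 3-ontology sets,
    readers for OBO flat files and a plain-text dictionary dialect, worked
    toy examples, and a seeded synthetic repository generator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    rlang,
    stringr,
    ggplot2,
    jsonlite,
    yaml,
    generics,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
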