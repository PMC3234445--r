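Package: morphokey
Title: Knowledge Bases and Free-Access Identification Keys for Morphological Taxonomy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building, validating and analysing structured
    descriptive knowledge bases (taxa described by multi-state categorical
    and numeric characters with polymorphism, unknown cells and
    inapplicability dependencies), as used in computer-aided taxonomic
    identification. Provides a free-access (multi-access) identification
    engine with elimination reasons and descriptor recommendation, pairwise
    description comparison for synonymy and consistency screening
    ('Checkbase'-style reports), unique-state ('special feature')
    extraction, comparative tables, a machine-readable mapping between
    classical archaeocyathan wall terminology and basic descriptors, a
    worked archaeocyathan fixture knowledge base, and a synthetic
    knowledge-base generator with planted ground truth for property
    testing. Knowledge bases are read and written as a documented JSON
    interchange format and as a CSV character-matrix dialect.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
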