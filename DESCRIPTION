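Package: rdfwikiforge
Title: Round-Trip Conversion Between RDF Graphs and Semantic Wiki Pages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Deterministic, lossless conversion of RDF triple data
    (N-Triples, and a documented Turtle subset) into a Semantic
    MediaWiki-style page structure: human-friendly page titles resolved
    from labels, namespace abbreviations or URI local parts; embedded
    property-value facts with inferred datatypes; auto-generated
    templates per rdf:type; and MediaWiki XML dumps. The inverse export
    reconstructs the originally imported triples through stored
    Equivalent-URI links, so that import followed by export returns the
    input graph exactly once wiki-added metadata is filtered out. Also
    provides chunked/restartable imports, in-place fact merging, a
    minimal triple-pattern store with LIMIT/OFFSET paging, a batched
    endpoint replicator, synthetic fixture generators shaped like
    biomedical linked-data sets (rare-disease gene associations,
    compound pKa measurements), and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stringi,
    stringr,
    tibble,
    utils,
    withr,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
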