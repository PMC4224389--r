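Package: ontobk
Title: Automated Background Knowledge Selection for Ontology Matching
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for lexical ontology matching and for automatically
    selecting background-knowledge ontologies that mediate indirect
    matches between a pair of input ontologies. Implements a weighted
    full-name lexical matcher over class labels and synonyms, indirect
    (mediated) matching through a third ontology, the mapping-gain,
    effectiveness and similarity-score metrics used to rank candidate
    background sources, a two-stage rank-and-select algorithm with a
    configurable gain threshold, greedy one-to-one alignment extraction,
    and precision/recall/F-measure evaluation against reference
    alignments. Reads OWL (RDF/XML) and OBO ontologies and OAEI-style
    alignment files, and ships a synthetic benchmark generator that
    builds matching problems with known ground truth.
License: MIT
Encoding: UTF-8
Imports:
    data.table,
    jsonlite,
    stats,
    stringi,
    utils,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
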