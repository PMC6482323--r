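Package: oncotext
Title: Text Mining of Cancer Therapy Literature for Drug Combinations and
    Cross-Species Candidate Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A literature-mining pipeline for comparative oncology. Selects
    candidate cancer genes by cross-referencing human-dog ortholog tables
    with a somatic-mutation catalog and builds the corresponding PubMed
    boolean queries from gene-synonym tables; classifies article abstracts
    as treatment success or failure with a random forest over word-trigram
    features; recognises drug and therapy names with a maximum-entropy
    per-token tagger plus a regular-expression false-positive filter;
    extracts drug combinations with cue-phrase rules applied to five-word
    context windows; and cross-references extracted drug names against
    offline drug-database tables. Includes a synthetic-corpus generator
    with ground truth so every stage is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    glmnet,
    ranger,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
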