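Package: kinasetriage
Title: Document Triage for Human Kinome Curation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ranks PubMed-style abstracts by their likelihood of containing a
    curatable relation between a target kinase and a disease or biological
    process. Provides readers and writers for PubTator-annotated corpora,
    candidate-triple tables, TREC run files and qrels; dictionary and
    regex-based entity tagging; entity-pair statistical and linguistic
    features (frequency, location, keyword, bag-of-words and dependency
    parse-path features) assembled into sparse document-term matrices;
    pseudo-negative bootstrapping with a one-class support vector machine;
    elastic-net logistic, binary SVM and one-class SVM ranking models; the
    full retrieval evaluation battery (precision and recall at fixed ranks,
    average precision, mean average precision, R-precision, maximum observed
    precision and a per-triple expected-rank score); and a synthetic corpus
    generator with planted, parameterised co-occurrence signal so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    Matrix,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
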