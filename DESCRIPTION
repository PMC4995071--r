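Package: beltools
Title: Parsing, Scoring and Corpus Tools for Biological Expression Language (BEL) Nanopubs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for corpora of BEL (Biological Expression Language 1.0)
    nanopublications: parse, validate and render BEL statements; canonicalize
    them under the BioCreative V BEL-track equivalence rules; score predicted
    against gold statements with a cascade precision/recall/F model at term,
    function, relationship and full-statement levels; read and write the
    tab-separated corpus and sentence-classification formats; apply the
    corpus-selection filter pipeline and compute corpus statistics;
    measure inter-annotator agreement (observed agreement and Cohen's kappa
    for label corpora, cascade F for statement corpora); retrieve candidate
    evidence sentences by trigger-word tri-occurrence; and generate synthetic
    nanopub corpora with controlled marginals for testing and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    caret,
    jsonlite
Config/testthat/edition: 3
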