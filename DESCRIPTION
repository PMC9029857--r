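Package: sigevolve
Title: Gene-Signature Discovery by Enrichment Screening and Genetic-Algorithm SVM Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers compact gene-expression signatures that separate two
    phenotype classes (designed around glioblastoma versus lower-grade glioma
    microarray cohorts). Genes are first screened by a signal-to-noise ranking
    combined with a running-sum gene-set enrichment score, yielding a candidate
    panel of over- and underexpressed genes. A genetic algorithm then searches
    binary gene subsets, scoring each chromosome by the cross-validated,
    grid-searched performance of an RBF-kernel support vector machine under
    four fitness measures (accuracy, Matthews correlation coefficient, F1, and
    a sensitivity plus weighted-specificity hybrid). Top solutions across
    repeated runs are aggregated into per-gene selective scores from which the
    final signature is extracted. Includes a seeded synthetic-data generator
    (two-class expression matrices with planted differential genes and a
    matching gene-set collection) so the whole pipeline is testable without
    external downloads, plus readers and writers for expression TSV, label CSV
    and GMT gene-set files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    e1071,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
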