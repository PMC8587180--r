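Package: cpctriage
Title: Corpus-Based Triage of Patient Question Texts into a Hierarchical
    Problem Taxonomy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies free-text patient questions into a hierarchical
    "cancer problem classification" style taxonomy by TF-IDF vectorization
    and cosine-similarity ranking against labeled reference corpora
    (category descriptions, labeled example questions, or their fusion).
    Ships the full evaluation protocol for such classifiers: multi-label
    top-k accuracy, k-fold cross-validation with mean/median/unbiased-SD
    aggregation, and Jensen-Shannon divergence between category
    distributions. Includes long-tail frequency reporting (rank-change
    curves, cumulative shares, top-N overlap), category-prefix and keyword
    filters for downstream signal extraction, a seeded synthetic-corpus
    generator for benchmarking without proprietary data, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    graphics,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
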