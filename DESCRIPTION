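Package: scfs
Title: Unsupervised Feature Selection by Standard Deviation and Cosine Similarity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised feature selection for high-dimensional, small-sample
    expression matrices. Each feature is scored as the product of its
    discernibility (sample standard deviation) and its independence (a
    decreasing function of the maximum absolute cosine similarity to features
    of higher discernibility), in three variants: exponential (SCEFS),
    reciprocal (SCRFS) and anti-cosine (SCAFS). Includes the matching
    evaluation protocol (stratified round-robin repeated k-fold
    cross-validation, KNN and linear SVM adapters, accuracy, AUC/MAUC,
    F2-measure, sensitivity and specificity with one-vs-one multiclass
    aggregation), Friedman rank tests with Nemenyi critical-difference
    post-hoc comparison, a synthetic-data generator with planted informative
    features, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
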