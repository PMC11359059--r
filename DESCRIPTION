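Package: psafl
Title: Federated Consensus Clustering for Post-Stroke Severity Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Unsupervised staging of post-stroke motor impairment from
    wearable or camera-based motion recordings, without sharing raw data
    across sites. Position trials are low-pass filtered and transformed into
    frequency-domain feature vectors; an ensemble of eight base clustering
    methods is combined through a co-association consensus matrix which is
    factorized by symmetric nonnegative matrix tri-factorization (multiplicative
    updates) into consensus cluster assignments; per-site cluster centroids are
    aligned by trunk-displacement severity rank and aggregated with federated
    averaging (FedAvg) into a global model that labels every subject with a
    severity level. Includes a seeded synthetic motion-cohort generator with
    known group structure, severity labeling against Fugl-Meyer Assessment
    reference categories, classification metrics, and computation/communication
    time bookkeeping.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    signal,
    e1071,
    mclust,
    kernlab,
    class,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
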