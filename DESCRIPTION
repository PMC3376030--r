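Package: optriclust
Title: Order-Preserving Triclustering of Short Time-Series Gene Expression Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Mines order-preserving triclusters (gene x sample x time) from
    3D short time-series gene expression data. Profiles are optionally
    quantized on a delta-grid, converted to dense rank vectors along the
    time dimension, and grouped by exact rank-signature identity over every
    admissible subset of biological samples, yielding conserved, constant
    and divergent temporal patterns together with a binomial-tail upper
    bound on tricluster significance. Includes a synthetic-data generator
    with embedded triclusters and an adjusted-Rand-index harness for
    noise-robustness evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    mclust,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
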