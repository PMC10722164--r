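Package: plastinet
Title: In Silico Neurodegeneration with Neuroplasticity for Convolutional Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates progressive, irreversible synaptic ablation of a
    convolutional object-recognition network interleaved with retraining of
    the surviving weights, as an in-silico model of neurodegeneration of the
    visual system (e.g. posterior cortical atrophy) equipped with a
    neuroplasticity mechanism. Provides a self-contained CPU implementation
    of sequential convolutional classifiers (convolution, batch
    normalization, max pooling, dense layers, SGD with momentum), a
    procedural stimulus generator so experiments run without external data,
    random synaptic injury schedules of the form 1-(1-gamma)^n, masked
    retraining that pins dead synapses at zero, structured L1 filter pruning
    to a target FLOP speedup, representational dissimilarity analysis
    (Pearson-distance RDMs compared by Kendall's tau), and a neural
    predictivity score based on PCA followed by partial least squares
    regression against (synthetic) neural recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    png,
    withr,
    mixOmics,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
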