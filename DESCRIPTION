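Package: pftp
Title: Partially Function-to-Topic Supervised Topic Models for Protein
    Function Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Multi-label prediction of protein function labels (GO terms)
    with a partially labeled supervised topic model.  Protein sequences are
    represented as bags of overlapping amino-acid k-mers; each function
    label owns a disjoint subset of latent topics and one shared background
    topic captures sequence features common to all proteins.  Training and
    fold-in prediction use a collapsed Gibbs sampler over joint
    (label, topic) token assignments; the package also provides a
    generative simulator for the model, multi-label ranking metrics
    (Hamming loss, one-error, average precision and three
    precision-recall-area summaries), and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    optparse,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
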