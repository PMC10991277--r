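Package: OGTpred
Title: Optimal-Temperature Regression from Protein Sequence and Thermophilic Enzyme Mining
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds optimal-growth-temperature-labelled protein corpora from FASTA
    and genome metadata, partitions them with ortholog-cluster-aware cross-validation
    folds so that homologous sequences never straddle a fold boundary, trains a
    one-hot convolutional regressor of a protein's optimal temperature (two
    convolution/max-pool blocks, two dropout-regularised dense layers, Adam with
    AMSGRAD, mean-squared-error loss, early stopping, grid search over kernel size
    and neuron count), evaluates predictions at the protein and genome level
    (Pearson correlation, mean absolute error, amino-acid-frequency correlation
    analysis), and screens metagenome-derived protein sets for candidate
    thermophilic enzymes from HMMER hmmsearch domain hits. Includes a synthetic
    corpus generator with a planted compositional temperature signal for
    desk-scale validation of the whole pipeline, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    S4Vectors,
    IRanges,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
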