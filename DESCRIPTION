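Package: cidkit
Title: Wolbachia cid-Gene Repertoire Inference and Cytoplasmic
    Incompatibility Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to infer Wolbachia wPip cidA/cidB gene repertoires from
    long-read amplicon sequencing and quantitative PCR, and to predict
    cytoplasmic-incompatibility (CI) cross outcomes under the toxin-antidote
    model. Includes reference-based variant assignment for noisy amplicon
    reads (cidA, cidB and tandem cidAB amplicons), fusion of wsp-normalised
    qPCR copy estimates with relative read coverage into integer per-variant
    copy numbers, (beta,16) genotype classification, a Gaussian-mixture
    coinfection screen, SNP-distance region nomenclature, recombinant
    (mosaic) region detection, hatch-rate statistics (binomial GLM likelihood
    ratio tests, Spearman, Levene), and a synthetic-data generator that
    emulates multi-copy repertoires, amplification bias, Nanopore-style read
    errors, qPCR replicate noise and overdispersed hatch rates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    Biostrings,
    mclust,
    car,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
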