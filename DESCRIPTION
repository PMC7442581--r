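Package: pollenftir
Title: Paraffin-Suppressed FTIR Classification of Single Pollen Grains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Chemometric pipeline for Fourier-transform infrared (FTIR)
    microspectra of individual paraffin-embedded grass pollen grains.
    Implements three strategies for suppressing the paraffin embedding
    signal -- omission of the 1300-1500 cm-1 region, joint non-negative
    matrix factorization (NMF) unmixing, and extended multiplicative
    signal correction (EMSC) with a paraffin constituent spectrum --
    together with asymmetric least squares (AsLS) baseline correction,
    Savitzky-Golay filtering, principal component analysis, Ward
    hierarchical clustering with Newick export, and PLS-DA, neural
    network and random forest classification under leave-one-out and
    independent-population validation. A hierarchical synthetic spectrum
    generator emulates the five-species, two-population study design for
    testing and method development.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    signal,
    ape,
    randomForest,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    withr
Config/testthat/edition: 3
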