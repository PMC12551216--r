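Package: genolex
Title: Linguistic-Statistical Analysis of Coding and Non-Coding DNA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Partitions an annotated genome into coding and non-coding
    regions and quantifies linguistic-statistical structure in each:
    Zipf rank-frequency analysis of k-mers with OLS and discrete
    maximum-likelihood power-law fits (Clauset-Shalizi-Newman xmin
    selection, Kolmogorov-Smirnov goodness of fit, AIC/BIC comparison
    against lognormal and exponential alternatives, bootstrap confidence
    intervals), purine-pyrimidine DNA-walk scaling exponents by rescaled
    range and detrended fluctuation analysis, Shannon block entropy and
    redundancy, Heaps' law, Zipf's law of abbreviation and Menzerath's
    law, with permutation and Markov-chain null models. Includes seeded
    generators for synthetic sequences and annotated toy genomes with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pracma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
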