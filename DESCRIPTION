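Package: selhmm
Title: General Diploid Selection Inference from Time-Series Allele Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hidden Markov model machinery for estimating general diploid
    selection coefficients (heterozygote and homozygote fitness effects)
    from temporally sampled allele counts, as arise in ancient-DNA time
    series and evolve-and-resequence experiments. Provides an
    expectation-maximization estimator with closed-form M-steps for the
    unconstrained model and for one-parameter selection modes (additive,
    dominant, recessive, heterozygote difference), likelihood-ratio tests
    and a multiple-alternative classification of the mode of selection,
    composite-likelihood estimation of the effective population size, a
    conditioned Wright-Fisher simulator, and a genome-scan layer with
    windowed p-value aggregation, FDR thresholds, region calling and
    parametric-bootstrap confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    vcfR
Config/testthat/edition: 3
LinkingTo: Rcpp
RoxygenNote: 7.3.3
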