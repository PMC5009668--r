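Package: coalstr
Title: Coalescent-Coupled Estimation of Short Tandem Repeat Copy Numbers
    from Paired-End Insert Sizes
Version: 0.1.0
Authors@R: person("coalstr", "maintainers", email = "coalstr@example.org",
    role = c("aut", "cre"))
Description: Estimates short tandem repeat (STR) copy numbers for multiple
    individuals jointly from paired-end insert-size data.  A per-individual
    likelihood compares inferred insert sizes against the library insert-size
    distribution; individuals are then coupled through coalescent genealogies
    sampled by MCMC from phased flanking genotypes, with repeat evolution on
    tree branches modelled by a Brownian approximation to the stepwise
    mutation model.  Decoding uses loopy followed by mixed-product belief
    propagation over the sampled tree ensemble.  Includes a coalescent
    simulator for benchmarking (Kingman trees, biallelic flanking sites,
    stepwise repeat evolution, direct insert-size simulation) and RMSE
    evaluation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    Rsamtools,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
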