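Package: gmatesim
Title: Stochastic Simulation of Genomic Mating Schemes in Closed Livestock Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Forward-in-time simulation of closed pig-like breeding programs
    under genomic selection, comparing traditional mate-allocation schemes
    (random, positive and negative assortative) with genomic mating plans
    optimized over an incidence-matrix objective trading expected progeny
    merit against expected progeny relatedness. Provides a configurable
    genome and founder simulator (mutation-drift equilibrated haplotypes),
    Mendelian gamete sampling under the Haldane map function, additive trait
    architectures with pedigree-recursive true breeding values, a BayesB
    marker-effect sampler for genomic prediction, SNP (VanRaden) and
    ROH-segment genomic relationship matrices, pedigree inbreeding by the
    tabular method, a hybrid genetic-algorithm/simulated-annealing
    mate-allocation optimizer with a nondominated gain-versus-inbreeding
    frontier, and a multi-generation experiment driver reporting rates of
    genetic gain and inbreeding.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
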