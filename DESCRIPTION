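Package: palaeopop
Title: Population-Genetic Analysis of Ancient Genomes Merged with Modern
    Reference Panels
Version: 0.1.0
Authors@R:
    person("palaeopop", "maintainers", email = "palaeopop@example.org",
           role = c("aut", "cre"))
Description: Tools for relating low-coverage ancient genomes to modern
    reference panels: pseudo-haploid genotype calling from read pileups
    with post-mortem damage handling, merging of ancient call sets into
    modern genotype or allele-frequency panels, D- and f3-statistics with
    weighted block jackknife standard errors, derived-allele sharing,
    admixture-proportion estimation by binomial-likelihood EM with
    projection of ancient samples onto fixed cluster allele frequencies,
    PCA with least-squares projection of partially missing samples, and
    divergence-time estimation from concordant and discordant gene-tree
    topologies.  Includes a Balding-Nichols allele-frequency simulator on
    population trees with admixture edges for validation against known
    ground truth, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    jsonlite,
    Rcpp,
    S4Vectors,
    stats,
    SummarizedExperiment,
    tools,
    utils,
    VariantAnnotation
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
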