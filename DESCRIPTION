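Package: dopanet
Title: Case-Control Association and Bayesian Network Relevance Analysis for
    Dopaminergic Gene Variants
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Candidate-gene case-control analysis for SNP and VNTR markers of
    the dopaminergic system: dominant-model chi-square association with odds
    ratios and Wald confidence intervals, Hardy-Weinberg goodness-of-fit
    diagnostics, Bonferroni correction, exact 2x2 tests and stratified
    two-locus analysis; EM haplotype frequency estimation from unphased
    genotypes with pairwise linkage-disequilibrium statistics (D, D', r2) and
    likelihood-ratio haplotype association; and a Bayesian-network-based
    Bayesian multilevel analysis (BN-BMLA) layer that samples directed acyclic
    graph structures by Markov chain Monte Carlo under the Cooper-Herskovits
    score and reports Markov blanket membership and set posteriors, edge
    posteriors, pairwise interaction/redundancy ratios, a consensus network
    and a relevance dendrogram. Includes a synthetic genotype generator with
    configurable linkage disequilibrium, logistic disease models, epistasis
    and mediation structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
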