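Package: dloopr
Title: Phylogeography of Mitochondrial D-Loop Sequences: Diversity,
    Haplotype Networks, Spatial Structure and ABC Scenario Choice
Version: 0.1.0
Authors@R: person("dloopr", "developers", email = "dloopr@example.org",
    role = c("aut", "cre"))
Description: An analysis pipeline for intraspecific phylogeography from
    aligned mitochondrial control-region (D-loop) sequences. Implements
    missing-data site filtering, haplotype collapsing, nucleotide and
    haplotype diversity, Tajima's D with beta-approximation significance,
    mismatch distributions with a Rogers-Harpending sudden-expansion fit
    and mutation-rate dating, median-joining haplotype networks,
    between-population net distances with neighbor-joining trees and
    midpoint rooting, AMOVA variance components and a SAMOVA-style
    simulated-annealing search for the K-group partition maximizing the
    among-group component, a haploid coalescent simulator with population
    splits and HKY+I+Gamma sequence evolution, and approximate Bayesian
    computation (rejection, multinomial-logistic scenario posterior
    probabilities, local-linear parameter posteriors) for comparing
    demographic scenarios.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ape,
    Biostrings,
    phangorn,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
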