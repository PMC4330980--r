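Package: drbnn
Title: Bayesian Neural Networks and MANOVA for Dose-Response Association
    Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects trait-associated genetic loci, including epistatic
    ones, in multi-dose cell-based dose-response studies. Implements a
    Bayesian neural network with an automatic relevance determination
    (ARD) prior sampled by Hamiltonian Monte Carlo with partial momentum
    refresh and annealed burn-in, a per-SNP multivariate analysis of
    variance (MANOVA) scan with Bonferroni selection as a comparator,
    three two-locus simulation models of SNP-driven dose-response
    (additive, additive with interaction, purely interactive), a
    replicate-level power-study harness, and closed-form marginal-effect
    analysis of the two-locus models with a brute-force enumeration
    oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    vcfR,
    ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
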