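Package: phydca
Title: Phyletic Direct Coupling Analysis of Domain Presence/Absence Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers direct pairwise couplings between protein-domain families
    from their binary presence/absence patterns across genomes (phylogenetic
    profiles) using a global maximum-entropy lattice-gas model. Couplings are
    estimated by mean-field covariance inversion or pseudo-likelihood
    maximization, optionally corrected by the average product correction, and
    ranked to predict domain-domain relationships. Includes classical
    correlation baselines (Hamming distance, Pearson correlation, Fisher's
    exact test), assembly of curated positive relation sets from five evidence
    classes, evaluation tools (positive predictive value curves, enrichment
    bins, prediction-set comparison, signed-network triangle census,
    correlation-versus-distance profiles), and a fully seeded synthetic
    generator sampling profile matrices from planted lattice-gas models for
    parameter-recovery studies.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    igraph,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
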