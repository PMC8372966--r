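Package: arboclim
Title: Climate Constraints on Arboreal Microhabitat Use Across a Phylogeny
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tests whether broad-scale climate constrains the use of the
    arboreal microhabitat across a clade. Provides per-species climate
    envelopes (five summary statistics for twelve bioclimatic variables),
    multivariate phylogenetic ANOVA by generalized least squares with
    randomized residual permutation (RRPP) and Holm sequential Bonferroni
    correction, an in-package presence-background maximum-entropy niche
    model with AUC evaluation, Schoener's D and Warren's I niche-overlap
    metrics, and a residualized pair-type permutation test that contrasts
    overlap among arboreal-arboreal, arboreal-terrestrial and
    terrestrial-terrestrial species pairs after removing geographic and
    phylogenetic distance effects. A synthetic-world generator (correlated
    spatially autocorrelated climate layers, pure-birth chronograms,
    asymmetric Markov microhabitat evolution, Brownian niche centers with
    an additive arboreal shift, Gaussian-suitability occurrence sampling)
    supplies inputs with known ground truth for calibration and power
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    geosphere,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
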