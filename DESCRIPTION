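Package: crlatent
Title: Consumer/Resource Latent-Space Generative Modeling of Host-Associated Microbiomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits a low-dimensional latent-variable model of microbial
    relative abundances derived from consumer/resource ecology, in which
    community compositions are log-linear functions of sample-specific
    latent variables and universal species preferences. Optionally couples
    a linear phenotype head so that the same latent variables explain host
    metadata. The fitted latent space is modeled with a BIC-selected
    Gaussian mixture, enabling generation of realistic in-silico
    microbiome/phenotype cohorts, phenotype-biased Markov chain Monte
    Carlo sampling for community design, prediction of compositions from
    partial phenotypes, and local (host-specific) correlation analysis.
    Includes compositional diagnostics (Bray-Curtis, Jensen-Shannon,
    Shannon diversity, species-abundance-distribution power laws) and a
    consumer/resource ODE simulator for ground-truth synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    deSolve
Suggests:
    testthat (>= 3.0.0),
    mclust,
    vegan
Config/testthat/edition: 3
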