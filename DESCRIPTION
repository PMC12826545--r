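Package: visrcomp
Title: Simulation and Compression-Dependence Analysis of Viscoelastic
    Response (VisR) Ultrasound
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to simulate and analyse Viscoelastic Response (VisR)
    acoustic radiation force impulse (ARFI) ultrasound studies of
    transversely isotropic soft tissue under surface compression.
    Generates seeded synthetic breast-tissue phantoms and radiofrequency
    (RF) speckle ensembles for a two-push ARFI sequence, tracks axial
    displacement by normalized cross-correlation with subsample
    interpolation, fits a mass-spring-damper model per pixel to estimate
    peak displacement (PD), relative elasticity (RE) and relative
    viscosity (RV), estimates the degree of anisotropy (DoA) by elliptical
    fitting across imaging angles, implements fixed and feature-matched
    focal regions of interest, and runs cohort-level nonparametric
    statistics (Kruskal-Wallis, Wilcoxon rank-sum, Bonferroni correction)
    on the resulting compression/density contrasts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
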