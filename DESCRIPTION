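Package: patchstat
Title: Spatial Statistics for Patchwork Quilt Patterns
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to quantify spatial order and randomness in patchwork
    quilts and similar tessellated artefacts. Provides polygon geometry and
    I/O for traced patch outlines, synthetic generators for regular
    (block-repeat) and crazy (irregular) quilts, maximum-likelihood fitting
    of unimodal area distributions (gamma, Weibull, lognormal, normal) with
    AIC ranking and Akaike weights, seeded Gaussian mixture models with
    Monte-Carlo sorted-area simulation envelopes, Strauss point-process
    modelling of patch centroids (Ripley K and L functions with isotropic
    edge correction, maximum pseudolikelihood fitting, fixed-n
    Metropolis-Hastings simulation and L-function envelopes), and
    two-sample group comparisons (Mann-Whitney U, Cohen's d).
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    e1071,
    fitdistrplus,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
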